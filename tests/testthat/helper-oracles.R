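# Independent brute-force oracles. These deliberately avoid the package's
# internal lookup tables: IUPAC expansion comes from Biostrings'
# IUPAC_CODE_MAP and every computation is a naive loop.

BASES <- c("A", "C", "G", "T")

.oracle_exp_cache <- new.env()
oracle_expand <- function(ch) {
  hit <- .oracle_exp_cache[[ch]]
  if (!is.null(hit)) return(hit)
  v <- if (ch == "-") character(0) else
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
  assign(ch, v, envir = .oracle_exp_cache)
  v
}

oracle_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ndiff <- 0L; ncomp <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% BASES && cb[i] %in% BASES) {
      ncomp <- ncomp + 1L
      if (ca[i] != cb[i]) ndiff <- ndiff + 1L
    }
  }
  list(p = if (ncomp > 0) ndiff / ncomp else NA_real_,
       ndiff = ndiff, ncomp = ncomp)
}

oracle_matrix <- function(records) {
  n <- nrow(records)
  p <- matrix(0, n, n); nd <- matrix(0L, n, n); nc <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- oracle_pdist(records$residues[i], records$residues[j])
    p[i, j] <- r$p; nd[i, j] <- r$ndiff; nc[i, j] <- r$ncomp
  }
  diag(p) <- 0
  list(p = p, ndiff = nd, ncomp = nc)
}

# min heterospecific distance per species by exhaustive pair scan
oracle_separation <- function(p, species, t) {
  sps <- unique(species)
  sep <- logical(length(sps)); names(sep) <- sps
  for (s in sps) {
    mn <- Inf
    for (i in which(species == s)) for (j in which(species != s)) {
      if (!is.na(p[i, j]) && p[i, j] < mn) mn <- p[i, j]
    }
    sep[s] <- is.finite(mn) && mn >= t
  }
  sep
}

oracle_problem_pairs <- function(p, species, cutoff) {
  sps <- unique(species)
  out <- list()
  for (a in seq_along(sps)) for (b in seq_along(sps)) {
    if (a >= b) next
    mn <- Inf
    for (i in which(species == sps[a])) for (j in which(species == sps[b])) {
      if (!is.na(p[i, j]) && p[i, j] < mn) mn <- p[i, j]
    }
    if (is.finite(mn) && mn < cutoff) {
      out[[length(out) + 1]] <- data.frame(species_a = sps[a],
                                           species_b = sps[b], min_p = mn)
    }
  }
  if (!length(out)) {
    return(data.frame(species_a = character(), species_b = character(),
                      min_p = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$min_p), , drop = FALSE]
}

oracle_variable_cols <- function(mat) {
  which(apply(mat, 2, function(col) length(unique(col[col %in% BASES])) >= 2))
}

# the single unambiguous base carried by all members at a column, else NA
oracle_uniform <- function(mat, member, col) {
  u <- unique(mat[member, col])
  if (length(u) == 1 && u %in% BASES) u else NA_character_
}

oracle_carried <- function(mat, rows, col, state) {
  any(vapply(mat[rows, col], function(ch) state %in% oracle_expand(ch),
             logical(1)))
}

# exhaustive diagnostic enumeration, orders 1-3, uniform joint-pattern
# semantics with minimality; returns data.frame(group, kind, columns, states).
# The per-site carrier mask is precomputed (naively, per cell) so the
# subset enumeration itself stays affordable at acceptance scale.
oracle_diagnostics <- function(mat, grouping, orders = 1:3) {
  vc <- oracle_variable_cols(mat)
  out <- list()
  add <- function(g, kind, cols, st) {
    out[[length(out) + 1]] <<- data.frame(
      group = g, kind = kind, columns = paste(cols, collapse = ","),
      states = paste(st, collapse = ","), stringsAsFactors = FALSE)
  }
  for (g in unique(grouping)) {
    member <- grouping == g
    if (!any(member) || all(member)) next
    orow <- which(!member)
    u <- vapply(vc, function(c) oracle_uniform(mat, member, c), character(1))
    carrier <- matrix(FALSE, length(orow), length(vc))
    for (oi in seq_along(orow)) {
      for (k in seq_along(vc)) {
        if (!is.na(u[k])) {
          carrier[oi, k] <- u[k] %in% oracle_expand(mat[orow[oi], vc[k]])
        }
      }
    }
    uniq <- !apply(carrier, 2, any)               # state unique to the group
    ok <- which(!is.na(u))
    # pairwise "some non-member carries both" table, computed directly
    J2 <- matrix(FALSE, length(vc), length(vc))
    for (a in ok) for (b in ok) {
      if (a < b) J2[a, b] <- J2[b, a] <- any(carrier[, a] & carrier[, b])
    }
    if (1 %in% orders) {
      for (k in ok) if (uniq[k]) add(g, "pure", vc[k], u[k])
    }
    if (2 %in% orders && length(ok) >= 2) {
      for (a in ok) for (b in ok) {
        if (a >= b) next
        if (uniq[a] || uniq[b]) next
        if (!J2[a, b]) add(g, "compound_pure", vc[c(a, b)], u[c(a, b)])
      }
    }
    if (3 %in% orders && length(ok) >= 3) {
      for (a in ok) for (b in ok) for (cc in ok) {
        if (a >= b || b >= cc) next
        if (uniq[a] || uniq[b] || uniq[cc]) next
        if (!J2[a, b] || !J2[a, cc] || !J2[b, cc]) next
        if (!any(carrier[, a] & carrier[, b] & carrier[, cc])) {
          add(g, "doubly_compound", vc[c(a, b, cc)], u[c(a, b, cc)])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(group = character(), kind = character(),
                      columns = character(), states = character()))
  }
  do.call(rbind, out)
}

oracle_private <- function(mat, grouping) {
  vc <- oracle_variable_cols(mat)
  out <- list()
  for (g in unique(grouping)) {
    member <- grouping == g
    if (!any(member) || all(member)) next
    orow <- which(!member)
    for (c in vc) for (s in BASES) {
      nm <- sum(mat[member, c] == s)
      if (nm >= 1 && nm < sum(member) && !oracle_carried(mat, orow, c, s)) {
        out[[length(out) + 1]] <- data.frame(group = g, columns = as.character(c),
                                             states = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(group = character(), columns = character(),
                      states = character()))
  }
  do.call(rbind, out)
}

# naive Hamming scan used to verify primer no-hit signals
oracle_primer_hit <- function(template, primer, max_mismatch) {
  tc <- strsplit(template, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  for (s in seq_len(length(tc) - length(pc) + 1)) {
    mm <- 0L
    for (i in seq_along(pc)) {
      if (!any(oracle_expand(pc[i]) %in% oracle_expand(tc[s + i - 1]))) {
        mm <- mm + 1L
      }
    }
    if (mm <= max_mismatch) return(s)
  }
  NA_integer_
}

# ---- random fixtures -------------------------------------------------------

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# random grouped alignment: a handful of founder patterns plus sprinkled
# substitutions, gaps and ambiguity codes; species sizes uneven
random_grouped_records <- function(n_seq, ncols, n_species = NULL,
                                   sub_rate = 0.04, gap_rate = 0.01,
                                   amb_rate = 0.01) {
  if (is.null(n_species)) n_species <- sample(2:max(2, n_seq %/% 2), 1)
  founders <- replicate(n_species, sample(BASES, ncols, replace = TRUE),
                        simplify = FALSE)
  sp <- sort(c(seq_len(n_species),
               sample(n_species, n_seq - n_species, replace = TRUE)))
  mat <- t(vapply(sp, function(i) {
    x <- founders[[i]]
    flip <- runif(ncols) < sub_rate
    x[flip] <- vapply(x[flip], function(b) sample(setdiff(BASES, b), 1), "")
    x[runif(ncols) < gap_rate] <- "-"
    x[runif(ncols) < amb_rate] <- sample(c("N", "R", "Y", "W"), 1)
    x
  }, character(ncols)))
  data.frame(id = sprintf("s%03d", seq_len(n_seq)),
             species = sprintf("sp%02d", sp),
             genus = sprintf("g%02d", ceiling(sp / 2)),
             group = NA_character_, strain = NA_character_,
             residues = apply(mat, 1, paste, collapse = ""),
             stringsAsFactors = FALSE)
}

seq_matrix_of <- function(records) {
  matrix(unlist(strsplit(records$residues, "")), nrow = nrow(records),
         byrow = TRUE)
}

# canonical "columns,states" keys for comparing diagnostic tables
diag_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$group, df$kind, df$columns, df$states, sep = "|"))
}
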