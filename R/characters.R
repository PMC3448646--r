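# Character-based diagnostics: variable sites, pure/compound/private
# diagnostic discovery, NJ guide tree, rule-based classification.

#' Variable sites of an alignment
#'
#' Columns that are polymorphic across the record set. By default only the
#' unambiguous bases `A`, `C`, `G`, `T` count as states (gap-only variation
#' is ignored); set `gap_as_state = TRUE` to treat the gap character as a
#' fifth state. The ordinal numbering (1, 2, ...) is the one used when
#' conserved stretches are collapsed in published figures; the absolute
#' alignment column is always reported alongside.
#'
#' @param records aligned record `data.frame`.
#' @param gap_as_state logical; count `-` as a state.
#' @return Data frame with columns `ordinal` and `column` (both 1-based),
#'   class `variable_sites`.
#' @export
variable_sites <- function(records, gap_as_state = FALSE) {
  mat <- seq_matrix(records)
  states <- if (gap_as_state) c(DNA_BASES, "-") else DNA_BASES
  poly <- apply(mat, 2, function(col) {
    length(unique(col[col %in% states])) >= 2
  })
  cols <- which(poly)
  structure(data.frame(ordinal = seq_along(cols), column = cols),
            class = c("variable_sites", "data.frame"))
}

# grouping: named character vector id -> group; default species labels
resolve_grouping <- function(records, grouping = NULL) {
  if (is.null(grouping)) {
    if (anyNA(records$species)) {
      stop("no grouping given and some records lack species labels",
           call. = FALSE)
    }
    grouping <- stats::setNames(records$species, records$id)
  }
  if (is.null(names(grouping)) || !all(records$id %in% names(grouping))) {
    stop("grouping must cover every record id", call. = FALSE)
  }
  grouping[records$id]
}

# does the IUPAC expansion of character ch contain base s?
# rows = A,C,G,T; cols = allowed characters ('-' contains nothing)
.contains_lookup <- local({
  m <- matrix(FALSE, 4, length(ALLOWED_CHARS),
              dimnames = list(DNA_BASES, ALLOWED_CHARS))
  for (ch in names(IUPAC_CODES)) m[IUPAC_CODES[[ch]], ch] <- TRUE
  m
})

# per-group machinery shared by the diagnostic searches:
# uniform[c]  = the single ACGT state carried by every member at column c
#               (NA when members disagree or any carries gap/ambiguity)
# carries[j,c]= TRUE when non-member j's expansion contains uniform[c]
group_profile <- function(mat, member, cols) {
  mem <- mat[member, cols, drop = FALSE]
  oth <- mat[!member, cols, drop = FALSE]
  uniform <- apply(mem, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1 && u %in% DNA_BASES) u else NA_character_
  })
  carries <- matrix(FALSE, nrow(oth), length(cols))
  ok <- which(!is.na(uniform))
  for (k in ok) {
    carries[, k] <- .contains_lookup[uniform[k], oth[, k]]
  }
  list(uniform = uniform, carries = carries)
}

diag_row <- function(group, kind, vs, cols_idx, states) {
  data.frame(group = group, kind = kind,
             ordinals = paste(vs$ordinal[cols_idx], collapse = ","),
             columns = paste(vs$column[cols_idx], collapse = ","),
             states = paste(states, collapse = ","),
             stringsAsFactors = FALSE)
}

empty_diag <- function() {
  data.frame(group = character(), kind = character(), ordinals = character(),
             columns = character(), states = character(),
             stringsAsFactors = FALSE)
}

#' Find pure diagnostic characters
#'
#' A pure diagnostic for a group is a single variable site at which every
#' group member carries the same unambiguous base and no non-member can
#' carry it (non-member ambiguity codes are IUPAC-expanded; any overlap
#' disqualifies). A gap or ambiguity code at the site in any member
#' disqualifies the site for that group.
#'
#' @param records aligned record `data.frame`.
#' @param grouping optional named character vector `id -> group`; defaults
#'   to the species labels.
#' @param vs precomputed [variable_sites()] (computed if missing).
#' @return Data frame of diagnostics: `group`, `kind`, `ordinals`,
#'   `columns`, `states` (site lists comma-joined, 1-based columns).
#' @export
find_pure_diagnostics <- function(records, grouping = NULL, vs = NULL) {
  records <- validate_records(records)
  grouping <- resolve_grouping(records, grouping)
  if (is.null(vs)) vs <- variable_sites(records)
  mat <- seq_matrix(records)
  out <- empty_diag()
  if (!nrow(vs)) return(out)
  for (g in unique(grouping)) {
    member <- grouping == g
    if (!any(member) || all(member)) next
    prof <- group_profile(mat, member, vs$column)
    hit <- which(!is.na(prof$uniform) & colSums(prof$carries) == 0)
    for (k in hit) {
      out <- rbind(out, diag_row(g, "pure", vs, k, prof$uniform[k]))
    }
  }
  out
}

#' Find compound diagnostic characters
#'
#' A compound pure diagnostic (order 2) is a pair of variable sites whose
#' joint states are carried by every group member while no non-member can
#' jointly carry both, and neither site alone is diagnostic. Order 3
#' (`doubly_compound`) extends this to three sites with no diagnostic
#' subset; following the published practice it may be used like a pure
#' diagnostic for classification. Sites already pure for the group are
#' excluded from the search. `triple_mode = "private"` additionally
#' requires, for order 3, that each site's state is found in some but not
#' all members and in no non-member when taken alone across the full
#' record set is impossible for a uniform pattern, so this mode instead
#' searches triples of individually *private* states (see
#' [find_private_characters()]) and reports them as
#' `doubly_compound_private`; the default `"any"` mode is the uniform
#' joint-pattern search used everywhere else.
#'
#' @inheritParams find_pure_diagnostics
#' @param order 2 or 3.
#' @param max_sites combinatorial cap on the number of candidate variable
#'   sites (default 200 for order 2, 80 for order 3); exceeding it is an
#'   error, never a silent truncation.
#' @param triple_mode order-3 site semantics, `"any"` (default) or
#'   `"private"`.
#' @return Data frame of diagnostics (see [find_pure_diagnostics()]).
#' @export
find_compound_diagnostics <- function(records, grouping = NULL, order = 2,
                                      vs = NULL, max_sites = NULL,
                                      triple_mode = c("any", "private")) {
  stopifnot(order %in% c(2, 3))
  triple_mode <- match.arg(triple_mode)
  records <- validate_records(records)
  grouping <- resolve_grouping(records, grouping)
  if (is.null(vs)) vs <- variable_sites(records)
  if (is.null(max_sites)) max_sites <- if (order == 2) 200L else 80L
  mat <- seq_matrix(records)
  out <- empty_diag()
  if (nrow(vs) < order) return(out)
  if (nrow(vs) > max_sites) {
    stop("combinatorial budget exceeded: ", nrow(vs),
         " variable sites > cap ", max_sites,
         "; raise max_sites explicitly to search anyway", call. = FALSE)
  }
  if (order == 3 && triple_mode == "private") {
    return(private_triples(records, grouping, vs, mat))
  }
  for (g in unique(grouping)) {
    member <- grouping == g
    if (!any(member) || all(member)) next
    prof <- group_profile(mat, member, vs$column)
    pure <- !is.na(prof$uniform) & colSums(prof$carries) == 0
    cand <- which(!is.na(prof$uniform) & !pure)
    if (length(cand) < order) next
    carries <- prof$carries[, cand, drop = FALSE] * 1
    # joint2[a,b] = number of non-members carrying both candidate sites
    joint2 <- crossprod(carries)
    if (order == 2) {
      idx <- which(joint2 == 0 & upper.tri(joint2), arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        ks <- cand[c(idx[r, 1], idx[r, 2])]
        out <- rbind(out, diag_row(g, "compound_pure", vs, ks,
                                   prof$uniform[ks]))
      }
    } else {
      nc <- length(cand)
      for (a in seq_len(nc - 2)) {
        sub <- carries[carries[, a] > 0, , drop = FALSE]
        joint3a <- crossprod(sub)   # [b,c] = non-members carrying a, b and c
        for (b in (a + 1):(nc - 1)) {
          if (joint2[a, b] == 0) next          # pair (a,b) already diagnostic
          for (cc in (b + 1):nc) {
            if (joint2[a, cc] == 0 || joint2[b, cc] == 0) next
            if (joint3a[b, cc] > 0) next       # some non-member matches all 3
            ks <- cand[c(a, b, cc)]
            out <- rbind(out, diag_row(g, "doubly_compound", vs, ks,
                                       prof$uniform[ks]))
          }
        }
      }
    }
  }
  out
}

# literal "three private characters at different variable sites": each
# (site, state) is private for the group; reported for audit/classification
# under the published modification that treats the triple as pure
private_triples <- function(records, grouping, vs, mat) {
  priv <- find_private_characters(records, grouping, vs)
  out <- empty_diag()
  for (g in unique(priv$group)) {
    pg <- priv[priv$group == g, , drop = FALSE]
    if (nrow(pg) < 3) next
    combos <- utils::combn(nrow(pg), 3)
    for (r in seq_len(ncol(combos))) {
      rows <- pg[combos[, r], ]
      if (length(unique(rows$columns)) < 3) next
      out <- rbind(out, data.frame(
        group = g, kind = "doubly_compound_private",
        ordinals = paste(rows$ordinals, collapse = ","),
        columns = paste(rows$columns, collapse = ","),
        states = paste(rows$states, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Find private characters
#'
#' A private character is a base found in at least one but not all members
#' of a group and in no non-member (after IUPAC expansion of non-member
#' codes). Private characters do not identify the whole group; they are
#' reported for audit since in curated data they frequently trace to
#' base-calling error.
#'
#' @inheritParams find_pure_diagnostics
#' @return Data frame of diagnostics with `kind = "private"`.
#' @export
find_private_characters <- function(records, grouping = NULL, vs = NULL) {
  records <- validate_records(records)
  grouping <- resolve_grouping(records, grouping)
  if (is.null(vs)) vs <- variable_sites(records)
  mat <- seq_matrix(records)
  out <- empty_diag()
  for (g in unique(grouping)) {
    member <- grouping == g
    if (!any(member) || all(member)) next
    mem <- mat[member, vs$column, drop = FALSE]
    oth <- mat[!member, vs$column, drop = FALSE]
    for (k in seq_along(vs$column)) {
      for (s in DNA_BASES) {
        n_mem <- sum(mem[, k] == s)
        if (n_mem < 1 || n_mem == nrow(mem)) next
        if (any(.contains_lookup[s, oth[, k]])) next
        out <- rbind(out, diag_row(g, "private", vs, k, s))
      }
    }
  }
  out
}

#' Build a character table for a grouping
#'
#' Convenience wrapper combining pure, compound (order 2) and
#' doubly-compound (order 3, default mode) diagnostics, ranked pure <
#' compound < doubly-compound within each group, plus private characters
#' for audit. The alignment width is attached so queries can be checked.
#'
#' @inheritParams find_compound_diagnostics
#' @param orders subset of `1:3`; which search orders to run.
#' @return Data frame of class `character_table` with attribute `ncols`.
#' @export
character_table <- function(records, grouping = NULL, orders = 1:3,
                            max_sites = NULL, triple_mode = "any") {
  records <- validate_records(records)
  vs <- variable_sites(records)
  parts <- list()
  if (1 %in% orders) parts$pure <- find_pure_diagnostics(records, grouping, vs)
  if (2 %in% orders) {
    parts$c2 <- find_compound_diagnostics(records, grouping, 2, vs, max_sites)
  }
  if (3 %in% orders) {
    parts$c3 <- find_compound_diagnostics(records, grouping, 3, vs, max_sites,
                                          triple_mode)
  }
  parts$priv <- find_private_characters(records, grouping, vs)
  tab <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  rank <- c(pure = 1, compound_pure = 2, doubly_compound = 3,
            doubly_compound_private = 3, private = 9)
  tab <- tab[order(tab$group, rank[tab$kind]), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, ncols = alignment_ncols(records),
            class = c("character_table", "data.frame"))
}

#' Neighbor-joining guide tree
#'
#' Standard NJ on the p-distance matrix (deterministic for a fixed id
#' order); used only as a guide for grouping sequences, not for inference.
#'
#' @param m a `p_dist` matrix with no undefined entries and at least 3
#'   sequences.
#' @param path optional file; when given the tree is written there in
#'   newick format.
#' @return An `ape::phylo` tree.
#' @export
build_guide_tree <- function(m, path = NULL) {
  if (length(m$ids) < 3) stop("need at least 3 sequences for NJ", call. = FALSE)
  if (anyNA(m$p)) stop("distance matrix has undefined entries", call. = FALSE)
  tree <- ape::nj(stats::as.dist(m$p))
  if (!is.null(path)) ape::write.tree(tree, path)
  tree
}

#' Derive a grouping from the guide tree
#'
#' Cuts an average-linkage clustering of the p-distance matrix into `k`
#' groups, as an alternative to species labels when labels are suspect.
#'
#' @param m a `p_dist` matrix.
#' @param k number of groups.
#' @return Named character vector `id -> group`.
#' @export
tree_grouping <- function(m, k) {
  cl <- stats::cutree(stats::hclust(stats::as.dist(m$p), method = "average"), k)
  stats::setNames(paste0("cluster", cl), m$ids)
}

#' Classify a sequence by diagnostic characters
#'
#' Returns every group whose full (non-private) diagnostic rule-set the
#' query satisfies: for each diagnostic, the query must carry exactly the
#' required base at every listed column (ambiguity codes in the query do
#' not match). A singleton result is an identification, a multi-group
#' result is ambiguous (groups inseparable by the table), an empty result
#' is unassigned.
#'
#' @param query residue string or single-row record, aligned to the
#'   reference alignment the table was derived from.
#' @param table a [character_table()] (or compatible data frame with
#'   attribute `ncols`).
#' @return Character vector of satisfied group labels, with attribute
#'   `matched` (per-group count of satisfied diagnostics).
#' @export
classify_sequence <- function(query, table) {
  seq <- if (is.character(query)) normalize_residues(query) else query$residues
  ncols <- attr(table, "ncols")
  if (!is.null(ncols) && nchar(seq) != ncols) {
    stop("query length ", nchar(seq), " does not match reference alignment (",
         ncols, " columns)", call. = FALSE)
  }
  qc <- strsplit(seq, "")[[1]]
  rules <- table[table$kind != "private", , drop = FALSE]
  groups <- unique(rules$group)
  hit <- character(0)
  matched <- integer(0)
  for (g in groups) {
    rg <- rules[rules$group == g, , drop = FALSE]
    ok <- vapply(seq_len(nrow(rg)), function(r) {
      cols <- as.integer(strsplit(rg$columns[r], ",")[[1]])
      st <- strsplit(rg$states[r], ",")[[1]]
      all(qc[cols] == st)
    }, logical(1))
    if (all(ok)) {
      hit <- c(hit, g)
      matched <- c(matched, sum(ok))
    }
  }
  attr(hit, "matched") <- stats::setNames(matched, hit)
  hit
}
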