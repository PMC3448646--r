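# Synthetic species-structured alignments with planted divergences,
# problem pairs, indel columns and diagnostic characters.

# Composition of per-column difference probabilities for substitution to a
# uniformly chosen different base: two independent stages with difference
# probabilities a and b give a + b - (4/3)ab (exact for this mutation
# kernel; 3/4 is the fixed point).
compose_div <- function(a, b) a + b - (4 / 3) * a * b

# per-stage mutation rate r so that two independent stages from a common
# source realize an expected pairwise difference d: 2r - (4/3)r^2 = d
rate_for <- function(d) {
  stopifnot(d >= 0, d <= 0.75)
  (3 / 4) * (1 - sqrt(1 - (4 / 3) * d))
}

#' Parameters for the synthetic alignment generator
#'
#' Defaults emulate a barcoding study of closely allied diatom species:
#' a 333-column V4-scale alignment, within-species divergence around
#' 0.004, between-species divergence around 0.08, occasional gap columns
#' and rare ambiguity codes. `intra_div` and `inter_div` are *pairwise
#' expected p-distances* (what a distance matrix should recover), not raw
#' per-sequence mutation rates; the generator converts them internally.
#'
#' @param n_species number of species.
#' @param seqs_per_species sequences per species (scalar or per-species
#'   vector).
#' @param ncols alignment columns.
#' @param intra_div expected within-species pairwise p-distance.
#' @param inter_div expected between-species pairwise p-distance.
#' @param n_problem_pairs species pairs whose founders are forced to
#'   distance at most `problem_p` (pairs are taken as species 1-2, 3-4, ...).
#' @param problem_p target ceiling for problem-pair founder distance;
#'   0 plants identical founders.
#' @param planted_characters list of planted diagnostics, each a list with
#'   `group`, `kind` (`"pure"`, `"compound_pure"`, `"doubly_compound"`),
#'   `columns` (1-based), `states`.
#' @param indel_rate per-column probability of a gap stripe in one species.
#' @param ambiguity_rate per-cell probability of an `N`.
#' @param species_per_genus genus labels group this many consecutive
#'   species.
#' @param seed mandatory integer seed.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_species = 20, seqs_per_species = 3, ncols = 333,
                         intra_div = 0.004, inter_div = 0.08,
                         n_problem_pairs = 0, problem_p = 0.003,
                         planted_characters = list(),
                         indel_rate = 0.01, ambiguity_rate = 0.002,
                         species_per_genus = 2, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_species >= 1, ncols >= 1,
            intra_div >= 0, intra_div < inter_div, inter_div <= 0.75,
            indel_rate >= 0, indel_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            problem_p >= 0, problem_p <= 1,
            n_problem_pairs >= 0, 2 * n_problem_pairs <= n_species)
  seqs <- rep_len(as.integer(seqs_per_species), n_species)
  structure(list(n_species = as.integer(n_species), seqs_per_species = seqs,
                 ncols = as.integer(ncols), intra_div = intra_div,
                 inter_div = inter_div,
                 n_problem_pairs = as.integer(n_problem_pairs),
                 problem_p = problem_p,
                 planted_characters = planted_characters,
                 indel_rate = indel_rate, ambiguity_rate = ambiguity_rate,
                 species_per_genus = as.integer(species_per_genus),
                 seed = as.integer(seed)),
            class = "synth_params")
}

# mutate: flip a Binomial(ncols, rate) random column subset, each to a
# uniformly chosen different base
mutate_seq <- function(chars, rate) {
  k <- stats::rbinom(1, length(chars), rate)
  if (k == 0) return(chars)
  cols <- sample.int(length(chars), k)
  for (c in cols) {
    chars[c] <- sample(setdiff(DNA_BASES, chars[c]), 1)
  }
  chars
}

# mutate exactly k distinct columns (used for problem-pair founders so the
# founder distance is exactly k/ncols)
mutate_exact <- function(chars, k) {
  if (k == 0) return(chars)
  cols <- sample.int(length(chars), k)
  for (c in cols) {
    chars[c] <- sample(setdiff(DNA_BASES, chars[c]), 1)
  }
  chars
}

#' Generate a synthetic species-structured alignment
#'
#' Draws a uniform ancestor, one founder per species, and star-topology
#' members around each founder, with per-stage mutation rates chosen so
#' that the *expected pairwise* within- and between-species p-distances
#' equal `intra_div` and `inter_div`. Problem-pair founders are copies
#' re-mutated at exactly `floor(problem_p * ncols)` columns. Gap stripes
#' and ambiguity codes are sprinkled afterwards; planted diagnostic
#' characters are written last and protected from all other noise. Fully
#' reproducible from the seed (the caller's RNG state is left untouched).
#'
#' @param params a [synth_params()] object.
#' @return List with `records` (labelled record `data.frame`) and `truth`
#'   (class `synth_truth`): species/genus per record, expected divergences,
#'   problem-pair list, planted characters, protected columns, params.
#' @export
generate_alignment <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  L <- params$ncols
  S <- params$n_species
  r_member <- rate_for(params$intra_div)
  f_founder <- (params$inter_div - params$intra_div) /
    (1 - (4 / 3) * params$intra_div)
  q_founder <- rate_for(f_founder)

  ancestor <- sample(DNA_BASES, L, replace = TRUE)
  founders <- lapply(seq_len(S), function(i) mutate_seq(ancestor, q_founder))

  pp <- list()
  if (params$n_problem_pairs > 0) {
    k_pp <- floor(params$problem_p * L)
    for (i in seq_len(params$n_problem_pairs)) {
      a <- 2 * i - 1; b <- 2 * i
      founders[[b]] <- mutate_exact(founders[[a]], k_pp)
      pp[[i]] <- c(a, b)
    }
  }

  sp_names <- sprintf("sp%02d", seq_len(S))
  genus <- sprintf("gen%02d", ceiling(seq_len(S) / params$species_per_genus))
  ids <- character(0); species <- character(0); gen_lab <- character(0)
  rows <- list()
  for (i in seq_len(S)) {
    for (j in seq_len(params$seqs_per_species[i])) {
      rows[[length(rows) + 1]] <- mutate_seq(founders[[i]], r_member)
      ids <- c(ids, sprintf("%s_%02d", sp_names[i], j))
      species <- c(species, sp_names[i])
      gen_lab <- c(gen_lab, genus[i])
    }
  }
  mat <- do.call(rbind, rows)

  protected <- integer(0)
  for (ch in params$planted_characters) protected <- c(protected, ch$columns)
  protected <- unique(protected)

  # gap stripes: each selected column gets gaps in a random nonempty
  # member subset of one random species
  gap_cols <- setdiff(which(stats::runif(L) < params$indel_rate), protected)
  for (c in gap_cols) {
    i <- sample.int(S, 1)
    mem <- which(species == sp_names[i])
    sub <- mem[stats::runif(length(mem)) < 0.6]
    if (!length(sub)) sub <- mem[sample.int(length(mem), 1)]
    mat[sub, c] <- "-"
  }
  amb <- which(matrix(stats::runif(length(mat)) < params$ambiguity_rate,
                      nrow(mat)), arr.ind = TRUE)
  amb <- amb[!amb[, 2] %in% protected, , drop = FALSE]
  mat[amb] <- "N"

  records <- data.frame(id = ids, species = species, genus = gen_lab,
                        group = NA_character_, strain = NA_character_,
                        residues = apply(mat, 1, paste, collapse = ""),
                        stringsAsFactors = FALSE)
  truth <- structure(list(
    species = stats::setNames(species, ids),
    genus = stats::setNames(gen_lab, ids),
    intra_div = params$intra_div, inter_div = params$inter_div,
    problem_pairs = if (length(pp)) {
      data.frame(species_a = sp_names[vapply(pp, function(x) x[1], numeric(1))],
                 species_b = sp_names[vapply(pp, function(x) x[2], numeric(1))],
                 founder_p = floor(params$problem_p * L) / L,
                 stringsAsFactors = FALSE)
    } else data.frame(species_a = character(), species_b = character(),
                      founder_p = numeric()),
    planted_characters = list(), protected_columns = protected,
    params = params
  ), class = "synth_truth")

  if (length(params$planted_characters)) {
    planted <- plant_diagnostics(records, truth, params$planted_characters)
    records <- planted$records
    truth <- planted$truth
  }
  list(records = records, truth = truth)
}

#' Plant diagnostic characters into an alignment
#'
#' Overwrites the alignment so that each requested character holds by
#' construction: group members carry the stated bases; for `pure` no
#' non-member carries the state; for `compound_pure`/`doubly_compound`
#' each proper subset of the sites is shared with at least one non-member
#' (so no subset is diagnostic) while no non-member matches the full joint
#' pattern. Deterministic (no RNG).
#'
#' @param records aligned record `data.frame`.
#' @param truth a `synth_truth` (or `NULL` when planting into arbitrary
#'   data).
#' @param characters list of characters as in [synth_params()].
#' @return List with updated `records` and `truth`.
#' @export
plant_diagnostics <- function(records, truth = NULL, characters = list()) {
  records <- validate_records(records)
  mat <- seq_matrix(records)
  L <- ncol(mat)
  grouping <- stats::setNames(records$species, records$id)

  seen <- list()  # column -> c(group, state) to detect conflicts
  for (ch in characters) {
    stopifnot(all(c("group", "kind", "columns", "states") %in% names(ch)))
    k <- length(ch$columns)
    if (!ch$kind %in% c("pure", "compound_pure", "doubly_compound") ||
        k != c(pure = 1, compound_pure = 2, doubly_compound = 3)[ch$kind] ||
        length(ch$states) != k) {
      stop("malformed planted character for group ", ch$group, call. = FALSE)
    }
    if (any(ch$columns < 1 | ch$columns > L)) {
      stop("planted column out of range for group ", ch$group, call. = FALSE)
    }
    if (!all(ch$states %in% DNA_BASES)) {
      stop("planted states must be unambiguous bases", call. = FALSE)
    }
    member <- grouping == ch$group
    if (!any(member)) stop("no such group: ", ch$group, call. = FALSE)
    # designated pattern groups are taken from the end of the group list so
    # planting composes with problem pairs, which occupy the front
    out_groups <- rev(setdiff(unique(grouping), ch$group))
    if (k > 1 && length(out_groups) < k) {
      stop("impossible constraint: planting a ", ch$kind, " needs at least ",
           k, " non-member groups", call. = FALSE)
    }
    for (i in seq_len(k)) {
      key <- as.character(ch$columns[i])
      prev <- seen[[key]]
      if (!is.null(prev) && !identical(prev, ch$states[i])) {
        stop("conflicting planted characters at column ", key, call. = FALSE)
      }
      seen[[key]] <- ch$states[i]
    }

    mrows <- which(member); orows <- which(!member)
    for (i in seq_len(k)) mat[mrows, ch$columns[i]] <- ch$states[i]
    other_base <- function(s) setdiff(DNA_BASES, s)[1]
    if (k == 1) {
      c1 <- ch$columns[1]; s1 <- ch$states[1]
      bad <- orows[.contains_lookup[s1, mat[orows, c1]]]
      mat[bad, c1] <- other_base(s1)
    } else {
      # every member of designated non-member group i matches every site
      # except site i; the k groups jointly cover all proper subsets while
      # none matches the full pattern. Whole groups are used so planting
      # never introduces within-group polymorphism.
      for (i in seq_len(k)) {
        grows <- which(grouping == out_groups[i])
        for (j in seq_len(k)) {
          mat[grows, ch$columns[j]] <- if (j == i) other_base(ch$states[j])
            else ch$states[j]
        }
      }
      rest <- setdiff(orows, which(grouping %in% out_groups[seq_len(k)]))
      for (o in rest) {
        full <- all(vapply(seq_len(k), function(j)
          .contains_lookup[ch$states[j], mat[o, ch$columns[j]]], logical(1)))
        if (full) mat[o, ch$columns[1]] <- other_base(ch$states[1])
      }
    }
  }

  records$residues <- apply(mat, 1, paste, collapse = "")
  if (!is.null(truth)) {
    truth$planted_characters <- characters
    truth$protected_columns <- unique(c(truth$protected_columns,
                                        unlist(lapply(characters, `[[`, "columns"))))
  }
  list(records = records, truth = truth)
}

#' Write generator truth to a JSON file
#'
#' @param truth a `synth_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$params <- unclass(out$params)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
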