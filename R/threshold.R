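# Threshold-based species separation, overlap counts, problem pairs.

species_of <- function(m, records) {
  records <- validate_records(records)
  stopifnot(identical(m$ids, records$id))
  miss <- records$id[is.na(records$species)]
  if (length(miss)) {
    stop("missing species label for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$species
}

# per-species minimum heterospecific distance and its nearest neighbour,
# plus the maximum intraspecific distance (0 for singletons)
species_stats <- function(m, sp) {
  species <- unique(sp)
  out <- data.frame(species = species, min_inter = NA_real_,
                    nearest = NA_character_, max_intra = 0,
                    n_seqs = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(species)) {
    mem <- sp == species[k]
    out$n_seqs[k] <- sum(mem)
    het <- m$p[mem, !mem, drop = FALSE]
    if (length(het)) {
      j <- which.min(het)
      if (length(j)) {
        out$min_inter[k] <- het[j]
        out$nearest[k] <- sp[!mem][(j - 1) %/% sum(mem) + 1]
      }
    }
    if (sum(mem) > 1) {
      intra <- m$p[mem, mem, drop = FALSE][upper.tri(diag(sum(mem)))]
      out$max_intra[k] <- suppressWarnings(max(intra, na.rm = TRUE))
      if (!is.finite(out$max_intra[k])) out$max_intra[k] <- NA_real_
    }
  }
  out
}

#' Species separation at a p-distance threshold
#'
#' Evaluates, for every species, whether the barcode separates it from all
#' heterospecifics at threshold `t`. Criteria:
#' \describe{
#'   \item{`nearest-neighbor` (default)}{species `s` separated iff the
#'     minimum distance from any of its sequences to any heterospecific
#'     sequence is `>= t` (a tie at exactly `t` counts as separated).}
#'   \item{`all-pairs`}{every heterospecific distance `>= t`; identical to
#'     nearest-neighbor, kept for symmetry.}
#'   \item{`barcode-gap`}{minimum heterospecific distance strictly greater
#'     than the species' own maximum intraspecific distance (0 for
#'     single-sequence species).}
#' }
#' The denominator of `fraction_separated` is all species; the overlap
#' count denominator is the species with two or more sequences. Both
#' conventions are echoed in the result.
#'
#' @param m a `p_dist` matrix.
#' @param records labelled records matching `m`.
#' @param t threshold proportion in \[0, 1\] (default 0.02).
#' @param criterion separation criterion, see above.
#' @param cutoff problem-pair cutoff passed to [problem_pairs()].
#' @return Object of class `separation_result` with `per_species` (data
#'   frame: species, n_seqs, min_inter, nearest, max_intra, separated),
#'   `fraction_separated`, `n_species`, `overlap` (see
#'   [intraspecific_overlap()]), `problem_pairs`, `t`, `criterion`.
#' @export
species_separation <- function(m, records, t = 0.02,
                               criterion = c("nearest-neighbor", "all-pairs",
                                             "barcode-gap"),
                               cutoff = 0.004) {
  criterion <- match.arg(criterion)
  stopifnot(t >= 0, t <= 1)
  sp <- species_of(m, records)
  if (length(unique(sp)) < 2) {
    stop("need at least 2 species to assess separation", call. = FALSE)
  }
  st <- species_stats(m, sp)
  st$separated <- switch(criterion,
    "nearest-neighbor" = ,
    "all-pairs" = st$min_inter >= t,
    "barcode-gap" = st$min_inter > st$max_intra
  )
  st$separated[is.na(st$separated)] <- FALSE
  structure(list(
    per_species = st,
    fraction_separated = mean(st$separated),
    n_species = nrow(st),
    overlap = intraspecific_overlap(m, records, t),
    problem_pairs = problem_pairs(m, records, cutoff),
    t = t, criterion = criterion
  ), class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("Species separation at t = %g (%s criterion)\n", x$t, x$criterion))
  cat(sprintf("  separated: %d / %d species (%.1f%%)\n",
              sum(x$per_species$separated), x$n_species,
              100 * x$fraction_separated))
  cat(sprintf("  intraspecific overlap: %d of %d multi-sequence species\n",
              x$overlap$count, x$overlap$n_multi))
  cat(sprintf("  problem pairs (min p < %g): %d\n",
              attr(x$problem_pairs, "cutoff"), nrow(x$problem_pairs)))
  invisible(x)
}

#' Species whose intraspecific variation reaches the threshold
#'
#' Counts species whose maximum intraspecific p-distance is `>= t`; the
#' denominator is the number of species represented by two or more
#' sequences. With no multi-sequence species the count is 0 and flagged.
#'
#' @inheritParams species_separation
#' @return List with `count`, `species` (offending labels), `n_multi` and
#'   `flagged` (TRUE when no species has multiple sequences).
#' @export
intraspecific_overlap <- function(m, records, t = 0.02) {
  sp <- species_of(m, records)
  st <- species_stats(m, sp)
  multi <- st[st$n_seqs > 1, , drop = FALSE]
  off <- multi$species[!is.na(multi$max_intra) & multi$max_intra >= t]
  list(count = length(off), species = off, n_multi = nrow(multi),
       flagged = nrow(multi) == 0)
}

#' Sweep separation statistics over a threshold grid
#'
#' @inheritParams species_separation
#' @param grid sorted numeric vector of thresholds.
#' @return Data frame with columns `t`, `fraction_separated`,
#'   `overlap_count`.
#' @export
threshold_sweep <- function(m, records, grid = c(0.01, 0.02),
                            criterion = "nearest-neighbor") {
  stopifnot(length(grid) >= 1, !is.unsorted(grid))
  rows <- lapply(grid, function(t) {
    r <- species_separation(m, records, t = t, criterion = criterion)
    data.frame(t = t, fraction_separated = r$fraction_separated,
               overlap_count = r$overlap$count)
  })
  do.call(rbind, rows)
}

#' Low-divergence species pairs
#'
#' Unordered species pairs whose minimum heterospecific distance falls
#' below `cutoff` (default p < 0.004, the scale at which pairs differ by at
#' most one or two sites over a 333-column barcode), sorted ascending.
#'
#' @inheritParams species_separation
#' @param cutoff strict upper bound on the minimum inter-pair distance.
#' @return Data frame `species_a`, `species_b`, `min_p`, with the cutoff
#'   attached as attribute `"cutoff"`.
#' @export
problem_pairs <- function(m, records, cutoff = 0.004) {
  sp <- species_of(m, records)
  species <- unique(sp)
  if (length(species) < 2) stop("need at least 2 species", call. = FALSE)
  out <- data.frame(species_a = character(), species_b = character(),
                    min_p = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(length(species) - 1)) {
    for (j in (i + 1):length(species)) {
      block <- m$p[sp == species[i], sp == species[j], drop = FALSE]
      mn <- suppressWarnings(min(block, na.rm = TRUE))
      if (is.finite(mn) && mn < cutoff) {
        out <- rbind(out, data.frame(species_a = species[i],
                                     species_b = species[j], min_p = mn,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$min_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}
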