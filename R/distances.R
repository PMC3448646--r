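# Uncorrected p-distances, K2P comparison, taxonomic partitioning.

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of compared sites at which the sequences differ. Under the
#' default pairwise-deletion policy a column is compared only when both
#' sequences carry an unambiguous base (`A`, `C`, `G`, `T`): gaps and IUPAC
#' ambiguity codes are excluded from the comparison, never partially
#' matched. With zero comparable sites the distance is undefined and
#' returned as `NA` with `flagged = TRUE`.
#'
#' @param a,b residue strings of equal length.
#' @return A list with `p`, `ndiff`, `ncomp` and `flagged`.
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(normalize_residues(a), "")[[1]]
  cb <- strsplit(normalize_residues(b), "")[[1]]
  if (length(ca) != length(cb)) {
    stop("sequences have unequal lengths (", length(ca), " vs ",
         length(cb), ")", call. = FALSE)
  }
  valid <- ca %in% DNA_BASES & cb %in% DNA_BASES
  ncomp <- sum(valid)
  ndiff <- sum(valid & ca != cb)
  list(p = if (ncomp > 0) ndiff / ncomp else NA_real_,
       ndiff = ndiff, ncomp = ncomp, flagged = ncomp == 0)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes transition (`P`) and transversion (`Q`) proportions over the
#' pairwise-deletion comparable sites and returns the closed form
#' `-1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. Included for the standard
#' sanity check that at barcoding-scale divergences the correction barely
#' moves the uncorrected distance.
#'
#' @param a,b residue strings of equal length.
#' @return The K2P distance (numeric scalar).
#' @export
k2p_distance <- function(a, b) {
  ca <- strsplit(normalize_residues(a), "")[[1]]
  cb <- strsplit(normalize_residues(b), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences have unequal lengths", call. = FALSE)
  valid <- ca %in% DNA_BASES & cb %in% DNA_BASES
  n <- sum(valid)
  if (n == 0) stop("no comparable sites", call. = FALSE)
  ca <- ca[valid]; cb <- cb[valid]
  diff <- ca != cb
  purine <- function(x) x %in% c("A", "G")
  ts <- sum(diff & purine(ca) == purine(cb))    # A<->G, C<->T
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop("K2P distance saturated (logarithm domain violation)", call. = FALSE)
  }
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

#' Pairwise p-distance matrix for an alignment
#'
#' All-against-all uncorrected p-distances with per-pair differing and
#' compared site counts. `gap_policy = "pairwise"` excludes gap/ambiguity
#' columns per pair; `"complete"` drops every column containing any
#' gap/ambiguity in any record before comparing. Pairs with zero
#' comparable sites get `p = NA` and are listed in `flagged`.
#'
#' @param records aligned record `data.frame`.
#' @param gap_policy `"pairwise"` (default) or `"complete"`.
#' @return Object of class `p_dist`: list with `ids`, symmetric matrices
#'   `p`, `ndiff`, `ncomp`, the `gap_policy` used and `flagged` (pair index
#'   matrix, possibly empty).
#' @export
distance_matrix <- function(records, gap_policy = c("pairwise", "complete")) {
  gap_policy <- match.arg(gap_policy)
  records <- validate_records(records)
  chars <- seq_matrix(records)
  if (gap_policy == "complete") {
    keep <- apply(chars, 2, function(col) all(col %in% DNA_BASES))
    chars <- chars[, keep, drop = FALSE]
  }
  n <- nrow(chars)
  ind <- lapply(DNA_BASES, function(b) (chars == b) * 1)
  valid <- Reduce(`+`, ind)
  ncomp <- valid %*% t(valid)
  same <- Reduce(`+`, lapply(ind, function(m) m %*% t(m)))
  ndiff <- ncomp - same
  p <- ifelse(ncomp > 0, ndiff / ncomp, NA_real_)
  diag(p) <- 0
  flagged <- which(ncomp == 0 & upper.tri(ncomp), arr.ind = TRUE)
  ids <- records$id
  dimnames(p) <- dimnames(ndiff) <- dimnames(ncomp) <- list(ids, ids)
  structure(list(ids = ids, p = p, ndiff = round(ndiff), ncomp = round(ncomp),
                 gap_policy = gap_policy, flagged = flagged),
            class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  cat("p-distance matrix:", length(x$ids), "sequences, gap policy:",
      x$gap_policy, "\n")
  offd <- x$p[upper.tri(x$p)]
  if (length(offd)) {
    cat(sprintf("  p range %.4f-%.4f, mean %.4f\n",
                min(offd, na.rm = TRUE), max(offd, na.rm = TRUE),
                mean(offd, na.rm = TRUE)))
  }
  if (nrow(x$flagged)) cat("  flagged (ncomp = 0) pairs:", nrow(x$flagged), "\n")
  invisible(x)
}

#' Partition pairwise distances by taxonomic level
#'
#' Each unordered sequence pair is intraspecific iff both records share a
#' species label, interspecific otherwise, and additionally intergeneric
#' when the genus labels differ. Intergeneric pairs therefore also appear
#' in the interspecific list; single-sequence species contribute no
#' intraspecific values.
#'
#' @param m a `p_dist` matrix.
#' @param records the records the matrix was computed from (labels used).
#' @return Object of class `distance_partition`: list of data frames
#'   `intraspecific`, `interspecific`, `intergeneric`, each with columns
#'   `id1`, `id2`, `species1`, `species2`, `p`.
#' @export
partition_distances <- function(m, records) {
  records <- validate_records(records)
  stopifnot(identical(m$ids, records$id))
  miss <- records$id[is.na(records$species) | is.na(records$genus)]
  if (length(miss)) {
    stop("missing species/genus label for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idx <- which(upper.tri(m$p), arr.ind = TRUE)
  pairs <- data.frame(
    id1 = m$ids[idx[, 1]], id2 = m$ids[idx[, 2]],
    species1 = records$species[idx[, 1]], species2 = records$species[idx[, 2]],
    genus1 = records$genus[idx[, 1]], genus2 = records$genus[idx[, 2]],
    p = m$p[idx], stringsAsFactors = FALSE
  )
  intra <- pairs$species1 == pairs$species2
  intergen <- pairs$genus1 != pairs$genus2
  keep <- c("id1", "id2", "species1", "species2", "p")
  structure(list(
    intraspecific = pairs[intra, keep, drop = FALSE],
    interspecific = pairs[!intra, keep, drop = FALSE],
    intergeneric = pairs[intergen, keep, drop = FALSE]
  ), class = "distance_partition")
}

#' Summary statistics for a set of p-distances
#'
#' @param values numeric vector of distances (NAs from flagged pairs are
#'   dropped with a warning).
#' @return Named numeric vector `min`, `max`, `mean`, `n`.
#' @export
summarize_distances <- function(values) {
  if (anyNA(values)) {
    warning("dropping ", sum(is.na(values)), " undefined distance(s)",
            call. = FALSE)
    values <- values[!is.na(values)]
  }
  if (!length(values)) stop("no distances to summarize", call. = FALSE)
  c(min = min(values), max = max(values), mean = mean(values),
    n = length(values))
}

#' @export
print.distance_partition <- function(x, ...) {
  cat("Distance partition (intergeneric pairs also counted interspecific)\n")
  for (lev in names(x)) {
    v <- x[[lev]]$p
    if (length(v)) {
      s <- suppressWarnings(summarize_distances(v))
      cat(sprintf("  %-14s n=%4d  min %.4f  mean %.4f  max %.4f\n",
                  lev, as.integer(s["n"]), s["min"], s["mean"], s["max"]))
    } else {
      cat(sprintf("  %-14s n=   0\n", lev))
    }
  }
  invisible(x)
}

#' Compare per-pair divergence between two regions
#'
#' For every sequence pair present in both matrices (e.g. the V4 barcode
#' versus a near-full-length 18S fragment of the same strains), reports the
#' p-distance and differing-site count in both, sorted by
#' `p_full - p_region` descending so pairs whose variability the short
#' region underestimates surface first.
#'
#' @param m_region,m_full `p_dist` matrices sharing at least two ids.
#' @return Data frame with `id1`, `id2`, `p_region`, `ndiff_region`,
#'   `p_full`, `ndiff_full`.
#' @export
compare_regions <- function(m_region, m_full) {
  shared <- intersect(m_region$ids, m_full$ids)
  if (length(shared) < 2) {
    stop("no shared sequence pairs between the two matrices", call. = FALSE)
  }
  idx <- utils::combn(shared, 2)
  out <- data.frame(
    id1 = idx[1, ], id2 = idx[2, ],
    p_region = m_region$p[cbind(idx[1, ], idx[2, ])],
    ndiff_region = m_region$ndiff[cbind(idx[1, ], idx[2, ])],
    p_full = m_full$p[cbind(idx[1, ], idx[2, ])],
    ndiff_full = m_full$ndiff[cbind(idx[1, ], idx[2, ])],
    stringsAsFactors = FALSE
  )
  out[order(out$p_full - out$p_region, decreasing = TRUE), , drop = FALSE]
}

#' Write a distance matrix to disk
#'
#' @param m a `p_dist` object.
#' @param path output file.
#' @param format `"tsv"` (square, id header row and column) or `"phylip"`
#'   (lower triangle).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(round(m$p, 6))
    df <- cbind(id = m$ids, df)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", length(m$ids)), con)
    for (i in seq_along(m$ids)) {
      row <- if (i > 1) paste(sprintf("%.6f", m$p[i, 1:(i - 1)]), collapse = " ") else ""
      writeLines(trimws(paste(format(m$ids[i], width = 10), row)), con)
    }
  }
  invisible(path)
}
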