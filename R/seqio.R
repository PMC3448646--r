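# Labelled sequence I/O, amplicon extraction and alignment hygiene.

#' Normalize residue strings
#'
#' Upper-cases, converts RNA `U` to `T`, accepts `.` as a gap alias (stored
#' as `-`) and rejects any character outside the IUPAC nucleotide alphabet
#' plus gap.
#'
#' @param x character vector of residue strings.
#' @param what label used in error messages (usually the record id).
#' @return Normalized character vector.
#' @export
normalize_residues <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- gsub(".", "-", x, fixed = TRUE)
  bad <- vapply(strsplit(x, ""), function(ch) any(!ch %in% ALLOWED_CHARS), logical(1))
  if (any(bad)) {
    stop("invalid residue characters in ", what, ": ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' Construct a labelled sequence record set
#'
#' Records are kept in an ordinary `data.frame` with columns `id`,
#' `species`, `genus`, `group`, `strain` and `residues`; all downstream
#' functions accept this layout. Ids must be unique and nonempty, residues
#' nonempty and drawn from the IUPAC alphabet plus gap.
#'
#' @param id,species,genus,group,strain,residues character vectors, recycled
#'   to the length of `id` where scalar.
#' @return A `data.frame` of records.
#' @export
seq_records <- function(id, species = NA_character_, genus = NA_character_,
                        group = NA_character_, strain = NA_character_,
                        residues = character()) {
  n <- length(id)
  rec <- data.frame(
    id = as.character(id),
    species = rep_len(as.character(species), n),
    genus = rep_len(as.character(genus), n),
    group = rep_len(as.character(group), n),
    strain = rep_len(as.character(strain), n),
    residues = as.character(residues),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
}

validate_records <- function(rec) {
  stopifnot(is.data.frame(rec), all(c("id", "residues") %in% names(rec)))
  if (any(is.na(rec$id) | !nzchar(rec$id))) {
    stop("record ids must be nonempty", call. = FALSE)
  }
  dup <- unique(rec$id[duplicated(rec$id)])
  if (length(dup)) {
    stop("duplicate record ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  empty <- rec$id[is.na(rec$residues) | !nzchar(rec$residues)]
  if (length(empty)) {
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  rec$residues <- normalize_residues(rec$residues, "records")
  for (col in c("species", "genus", "group", "strain")) {
    if (is.null(rec[[col]])) rec[[col]] <- NA_character_
  }
  rownames(rec) <- NULL
  rec
}

#' Read a labelled FASTA file
#'
#' Labels come either from pipe-delimited headers
#' (`id|species|genus|group`, trailing fields optional) or from a TSV
#' side-table with columns `id`, `species` and optionally `genus`, `group`,
#' `strain`, `accession`. When both are present the side-table wins.
#' Headers that carry no species field are kept with `species = NA` and
#' reported in a warning rather than dropped.
#'
#' @param path FASTA file.
#' @param metadata optional path to a metadata TSV (header row required).
#' @param sep header field delimiter, default `"|"`.
#' @return A record `data.frame` (see [seq_records()]).
#' @export
read_labeled_fasta <- function(path, metadata = NULL, sep = "|") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no sequences in ", path, call. = FALSE)
  headers <- names(set)
  fields <- strsplit(headers, sep, fixed = TRUE)
  pick <- function(i) vapply(fields, function(f) {
    if (length(f) >= i && nzchar(f[i])) f[i] else NA_character_
  }, character(1))
  rec <- data.frame(
    id = trimws(pick(1)),
    species = trimws(pick(2)),
    genus = trimws(pick(3)),
    group = trimws(pick(4)),
    strain = NA_character_,
    residues = as.character(set),
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata)) {
    meta <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                              colClasses = "character")
    if (!all(c("id", "species") %in% names(meta))) {
      stop("metadata table needs at least columns 'id' and 'species'",
           call. = FALSE)
    }
    idx <- match(rec$id, meta$id)
    for (col in intersect(c("species", "genus", "group", "strain"), names(meta))) {
      hit <- !is.na(idx)
      rec[[col]][hit] <- meta[[col]][idx[hit]]
    }
  }
  unlab <- rec$id[is.na(rec$species)]
  if (length(unlab)) {
    warning("records without species labels (kept, flagged): ",
            paste(unlab, collapse = ", "), call. = FALSE)
  }
  validate_records(rec)
}

#' Write records as labelled FASTA
#'
#' Headers are `id|species|genus|group` (empty trailing fields written as
#' empty strings so a round-trip reproduces the labels); sequences wrapped
#' at 80 columns.
#'
#' @param records record `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labeled_fasta <- function(records, path) {
  records <- validate_records(records)
  lab <- function(x) ifelse(is.na(x), "", x)
  headers <- paste(records$id, lab(records$species), lab(records$genus),
                   lab(records$group), sep = "|")
  headers <- sub("\\|+$", "", headers)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Apply species-label overrides
#'
#' Re-labels records whose identity was corrected after morphological
#' reassessment. Overrides are given as a data frame (or TSV path) with
#' columns `id`, `species` and optionally `genus`. Every override id must
#' match a record; unmatched keys are an error so typos cannot silently
#' drop a correction.
#'
#' @param records record `data.frame`.
#' @param overrides data frame or TSV path.
#' @return A list with `records` (relabelled) and `audit` (one row per
#'   changed record: id, field, old, new).
#' @export
apply_overrides <- function(records, overrides) {
  records <- validate_records(records)
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- utils::read.delim(overrides, stringsAsFactors = FALSE,
                                   colClasses = "character")
  }
  audit <- data.frame(id = character(), field = character(),
                      old = character(), new = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(overrides)) return(list(records = records, audit = audit))
  stopifnot(all(c("id", "species") %in% names(overrides)))
  missing <- setdiff(overrides$id, records$id)
  if (length(missing)) {
    stop("override id(s) match no record: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (k in seq_len(nrow(overrides))) {
    i <- match(overrides$id[k], records$id)
    for (field in intersect(c("species", "genus"), names(overrides))) {
      new <- overrides[[field]][k]
      if (is.na(new) || !nzchar(new)) next
      old <- records[[field]][i]
      if (!identical(old, new)) {
        audit <- rbind(audit, data.frame(id = records$id[i], field = field,
                                         old = old, new = new,
                                         stringsAsFactors = FALSE))
        records[[field]][i] <- new
      }
    }
  }
  list(records = records, audit = audit)
}

#' Define a PCR primer pair
#'
#' Both primers are written 5'-3' as on an order sheet; the reverse primer
#' anneals to the forward strand after reverse complementation. Matching is
#' Hamming distance (no indels) over IUPAC-expanded characters.
#'
#' @param forward,reverse primer sequences (IUPAC codes allowed).
#' @param max_mismatch mismatches tolerated per primer (default 2).
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 2L) {
  forward <- gsub(" ", "", forward)
  reverse <- gsub(" ", "", reverse)
  forward <- normalize_residues(forward, "forward primer")
  reverse <- normalize_residues(reverse, "reverse primer")
  if (!nzchar(forward) || !nzchar(reverse) ||
      grepl("-", forward) || grepl("-", reverse)) {
    stop("primers must be nonempty and ungapped", call. = FALSE)
  }
  stopifnot(max_mismatch >= 0)
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' D512/D978 primer pair targeting the 18S V4 region
#'
#' The standard diatom V4 primer pair (forward D512, reverse D978), exposed
#' as a convenience default for [extract_amplicon()].
#'
#' @param max_mismatch mismatches tolerated per primer.
#' @return A `primer_pair`.
#' @export
d512_d978 <- function(max_mismatch = 2L) {
  primer_pair("ATTCCAGCTCCAATAGCG", "GACTACGATGGTATCTAATC", max_mismatch)
}

#' Extract the inter-primer amplicon from an unaligned template
#'
#' Performs in-silico PCR: finds the leftmost forward-primer site, then the
#' nearest downstream site of the reverse-complemented reverse primer, and
#' returns the subsequence strictly between them (primer sequences removed).
#' Matching tolerates up to `max_mismatch` Hamming mismatches per primer
#' with IUPAC expansion on both strands. Returns `NULL` (no-hit) when
#' either primer is not found within budget or the reverse site does not
#' lie downstream of the forward site.
#'
#' @param record a single-row record `data.frame` or a residue string.
#' @param primers a [primer_pair()].
#' @return The amplicon as a record (labels preserved) or residue string,
#'   or `NULL` on no-hit.
#' @export
extract_amplicon <- function(record, primers = d512_d978()) {
  as_string <- is.character(record)
  seq <- if (as_string) normalize_residues(record, "template") else {
    record <- validate_records(record)
    stopifnot(nrow(record) == 1)
    record$residues
  }
  if (grepl("-", seq)) stop("template must be ungapped", call. = FALSE)
  subject <- Biostrings::DNAString(seq)
  hit1 <- Biostrings::matchPattern(Biostrings::DNAString(primers$forward),
                                   subject, max.mismatch = primers$max_mismatch,
                                   fixed = FALSE)
  if (!length(hit1)) return(NULL)
  fwd_end <- Biostrings::end(hit1)[1]
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  hit2 <- Biostrings::matchPattern(rc, subject,
                                   max.mismatch = primers$max_mismatch,
                                   fixed = FALSE)
  starts <- Biostrings::start(hit2)
  starts <- starts[starts > fwd_end]
  if (!length(starts)) return(NULL)
  rev_start <- min(starts)
  if (rev_start - 1 < fwd_end + 1) return(NULL)
  amp <- substr(seq, fwd_end + 1, rev_start - 1)
  if (as_string) return(amp)
  record$residues <- amp
  record
}

#' Trim an alignment to its core columns
#'
#' Keeps a contiguous column slice, by default columns 1..333 of the
#' primer-trimmed amplicon alignment (the V4 core plus flanks after the
#' super-conserved downstream region is dropped). Coordinates are 1-based
#' and closed.
#'
#' @param records aligned record `data.frame`.
#' @param start first column kept (default 1).
#' @param length number of columns kept (default 333).
#' @return Trimmed records.
#' @export
trim_to_core <- function(records, start = 1L, length = 333L) {
  records <- validate_records(records)
  ncols <- alignment_ncols(records)
  start <- as.integer(start); length <- as.integer(length)
  if (start < 1 || length < 1 || start + length - 1 > ncols) {
    stop("trim slice [", start, ", ", start + length - 1,
         "] out of range for ", ncols, " columns", call. = FALSE)
  }
  records$residues <- substr(records$residues, start, start + length - 1)
  records
}

#' Number of columns of an aligned record set
#'
#' @param records record `data.frame`; all residues must be equal length.
#' @return Integer column count.
#' @export
alignment_ncols <- function(records) {
  len <- nchar(records$residues)
  if (length(unique(len)) != 1) {
    off <- records$id[len != len[1]]
    stop("records not aligned (length mismatch): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  len[1]
}

#' Collapse identical sequences
#'
#' The first occurrence of each distinct residue string is kept as the
#' representative; the multiplicity map gives, per representative id, how
#' many input records carried that exact sequence (the bracketed counts of
#' collapsed-tree figures).
#'
#' @param records record `data.frame` (aligned or equal-length).
#' @return A list with `records` (uniques, input order) and `multiplicity`
#'   (named integer vector over representative ids).
#' @export
deduplicate <- function(records) {
  records <- validate_records(records)
  key <- records$residues
  first <- !duplicated(key)
  rep_id <- records$id[first][match(key, key[first])]
  mult <- table(factor(rep_id, levels = records$id[first]))
  list(records = records[first, , drop = FALSE],
       multiplicity = stats::setNames(as.integer(mult), names(mult)))
}

#' Validate an alignment and report anomalies
#'
#' Hard error on length mismatches; otherwise reports all-gap columns (with
#' a warning) and the ambiguity-code frequency per record. A clean
#' alignment yields an empty report.
#'
#' @param records aligned record `data.frame`.
#' @return A list of class `alignment_report` with elements `ncols`,
#'   `all_gap_columns` (1-based) and `ambiguity` (per-id counts, only ids
#'   with at least one ambiguity code).
#' @export
validate_alignment <- function(records) {
  records <- validate_records(records)
  ncols <- alignment_ncols(records)
  mat <- seq_matrix(records)
  all_gap <- which(apply(mat == "-", 2, all))
  if (length(all_gap)) {
    warning("all-gap column(s) at 1-based position(s): ",
            paste(all_gap, collapse = ", "), call. = FALSE)
  }
  amb_chars <- setdiff(names(IUPAC_CODES), DNA_BASES)
  amb <- apply(mat, 1, function(r) sum(r %in% amb_chars))
  names(amb) <- records$id
  amb <- amb[amb > 0]
  structure(list(ncols = ncols, all_gap_columns = as.integer(all_gap),
                 ambiguity = amb),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("Alignment report (1-based, closed coordinates)\n")
  cat("  columns:", x$ncols, "\n")
  if (length(x$all_gap_columns)) {
    cat("  all-gap columns:", paste(x$all_gap_columns, collapse = ", "), "\n")
  }
  if (length(x$ambiguity)) {
    cat("  ambiguity codes per record:\n")
    for (id in names(x$ambiguity)) cat("    ", id, ": ", x$ambiguity[[id]], "\n", sep = "")
  }
  if (!length(x$all_gap_columns) && !length(x$ambiguity)) {
    cat("  no anomalies\n")
  }
  invisible(x)
}

# character matrix view of an aligned record set (rows = records)
seq_matrix <- function(records) {
  ncols <- alignment_ncols(records)
  mat <- matrix(unlist(strsplit(records$residues, ""), use.names = FALSE),
                nrow = nrow(records), ncol = ncols, byrow = TRUE)
  rownames(mat) <- records$id
  mat
}
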