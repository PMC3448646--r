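# Pipeline orchestration, report bundle, run summary and CLI.

#' Configuration for a full barcode evaluation run
#'
#' Every effective parameter is echoed verbatim into the run manifest so a
#' bundle is reproducible from its manifest plus inputs alone.
#'
#' @param fasta input FASTA path (aligned unless primers are given).
#' @param metadata optional metadata TSV path.
#' @param overrides optional label-override TSV path.
#' @param primers optional [primer_pair()]; when given, each input record
#'   is an unaligned template and the inter-primer amplicon is extracted
#'   first (the extracted set must then be collinear).
#' @param trim_start,trim_length optional core-trim policy (1-based).
#' @param gap_policy `"pairwise"` or `"complete"`.
#' @param thresholds thresholds for the separation sweep.
#' @param primary_t threshold used for the headline separation figure.
#' @param criterion separation criterion.
#' @param cutoff problem-pair cutoff.
#' @param orders diagnostic search orders (subset of 1:3; default 1:2 —
#'   the order-3 search is exhaustive over site triples and is meant for
#'   low-divergence subsets with few variable sites, so it is opt-in).
#' @param max_sites combinatorial cap override for the character searches.
#' @param out_dir output directory (created if needed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(fasta, metadata = NULL, overrides = NULL,
                       primers = NULL, trim_start = NULL, trim_length = NULL,
                       gap_policy = "pairwise",
                       thresholds = c(0.01, 0.02), primary_t = 0.02,
                       criterion = "nearest-neighbor", cutoff = 0.004,
                       orders = 1:2, max_sites = NULL, out_dir) {
  for (p in c(fasta, metadata, overrides)) {
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  stopifnot(all(thresholds >= 0 & thresholds <= 1),
            primary_t >= 0, primary_t <= 1)
  structure(list(fasta = fasta, metadata = metadata, overrides = overrides,
                 primers = primers, trim_start = trim_start,
                 trim_length = trim_length, gap_policy = gap_policy,
                 thresholds = sort(thresholds), primary_t = primary_t,
                 criterion = criterion, cutoff = cutoff, orders = orders,
                 max_sites = max_sites, out_dir = out_dir),
            class = "run_config")
}

#' Run the full distance + threshold + character pipeline
#'
#' Reads and labels the sequences, applies overrides, optionally extracts
#' and trims the amplicon, then computes the distance matrix, taxonomic
#' partition, threshold sweep, problem pairs, diagnostic character table,
#' NJ guide tree (on deduplicated sequences) and a rule-based
#' classification of every sequence, writing each artifact as TSV/newick
#' plus a JSON manifest. Distance and threshold statistics use the full
#' record set including duplicates; deduplication applies only to the
#' guide tree.
#'
#' @param cfg a [run_config()].
#' @return The report bundle (named list of objects and file paths),
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  records <- read_labeled_fasta(cfg$fasta, metadata = cfg$metadata)
  audit <- NULL
  if (!is.null(cfg$overrides)) {
    ov <- apply_overrides(records, cfg$overrides)
    records <- ov$records
    audit <- ov$audit
  }
  if (!is.null(cfg$primers)) {
    amps <- lapply(seq_len(nrow(records)), function(i) {
      extract_amplicon(records[i, , drop = FALSE], cfg$primers)
    })
    no_hit <- records$id[vapply(amps, is.null, logical(1))]
    if (length(no_hit)) {
      warning("no amplicon for: ", paste(no_hit, collapse = ", "),
              call. = FALSE)
    }
    records <- do.call(rbind, amps[!vapply(amps, is.null, logical(1))])
  }
  if (!is.null(cfg$trim_start) || !is.null(cfg$trim_length)) {
    records <- trim_to_core(records,
                            start = cfg$trim_start %||% 1L,
                            length = cfg$trim_length %||% 333L)
  }
  report <- withCallingHandlers(
    validate_alignment(records),
    warning = function(w) invokeRestart("muffleWarning")
  )

  m <- distance_matrix(records, gap_policy = cfg$gap_policy)
  part <- partition_distances(m, records)
  sweep <- threshold_sweep(m, records, grid = cfg$thresholds,
                           criterion = cfg$criterion)
  sep <- species_separation(m, records, t = cfg$primary_t,
                            criterion = cfg$criterion, cutoff = cfg$cutoff)
  tab <- character_table(records, orders = cfg$orders,
                         max_sites = cfg$max_sites)
  dedup <- deduplicate(records)
  tree <- if (nrow(dedup$records) >= 3) {
    m_u <- distance_matrix(dedup$records, gap_policy = cfg$gap_policy)
    if (anyNA(m_u$p)) NULL else build_guide_tree(m_u)
  } else NULL
  cls <- data.frame(
    id = records$id, species = records$species,
    assigned = vapply(records$residues, function(s) {
      paste(classify_sequence(s, tab), collapse = ";")
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    distance_matrix = file.path(cfg$out_dir, "distance_matrix.tsv"),
    partition = file.path(cfg$out_dir, "partition_summary.tsv"),
    sweep = file.path(cfg$out_dir, "threshold_sweep.tsv"),
    problem_pairs = file.path(cfg$out_dir, "problem_pairs.tsv"),
    characters = file.path(cfg$out_dir, "character_table.tsv"),
    classification = file.path(cfg$out_dir, "classification.tsv"),
    tree = file.path(cfg$out_dir, "guide_tree.nwk"),
    manifest = file.path(cfg$out_dir, "manifest.json")
  )
  write_distance_matrix(m, paths$distance_matrix)
  part_sum <- do.call(rbind, lapply(names(part), function(lev) {
    v <- part[[lev]]$p
    if (!length(v)) {
      return(data.frame(category = lev, min = NA, max = NA, mean = NA, n = 0))
    }
    s <- suppressWarnings(summarize_distances(v))
    data.frame(category = lev, min = round(s[["min"]], 4),
               max = round(s[["max"]], 4), mean = round(s[["mean"]], 4),
               n = as.integer(s[["n"]]))
  }))
  utils::write.table(part_sum, paths$partition, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sweep, paths$sweep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sep$problem_pairs, paths$problem_pairs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(tab), paths$characters, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cls, paths$classification, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tree)) ape::write.tree(tree, paths$tree) else paths$tree <- NULL

  manifest <- list(
    package = "v4barcode",
    version = as.character(utils::packageVersion("v4barcode")),
    config = lapply(unclass(cfg), function(x) if (inherits(x, "primer_pair"))
      unclass(x) else x),
    coordinates = "1-based, closed",
    n_sequences = nrow(records), n_species = length(unique(records$species)),
    input_md5 = unname(tools::md5sum(cfg$fasta)),
    overrides_applied = if (is.null(audit)) 0L else nrow(audit)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)

  invisible(list(records = records, matrix = m, partition = part,
                 sweep = sweep, separation = sep, characters = tab,
                 classification = cls, tree = tree, audit = audit,
                 validation = report, multiplicity = dedup$multiplicity,
                 paths = paths, config = cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-page text summary of a pipeline run
#'
#' Splits the species three ways: separated by distance at the primary
#' threshold, not separated but carrying at least one (non-private)
#' diagnostic character ("rescued"), and unresolved by both approaches.
#'
#' @param bundle the list returned by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
summarize_run <- function(bundle) {
  need <- c("records", "partition", "sweep", "separation", "characters")
  miss <- setdiff(need, names(bundle)[!vapply(bundle, is.null, logical(1))])
  if (length(miss)) {
    stop("incomplete bundle, missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rec <- bundle$records
  sep <- bundle$separation
  per <- sep$per_species
  has_char <- per$species %in%
    bundle$characters$group[bundle$characters$kind != "private"]
  rescued <- !per$separated & has_char
  unresolved <- !per$separated & !has_char
  lines <- c(
    "v4barcode run summary (coordinates 1-based, closed)",
    sprintf("sequences: %d   species: %d   genera: %d", nrow(rec),
            length(unique(rec$species)), length(unique(rec$genus))),
    vapply(names(bundle$partition), function(lev) {
      v <- bundle$partition[[lev]]$p
      if (!length(v)) return(sprintf("%s: n=0", lev))
      s <- suppressWarnings(summarize_distances(v))
      sprintf("%s: n=%d min=%.4f mean=%.4f max=%.4f", lev,
              as.integer(s[["n"]]), s[["min"]], s[["mean"]], s[["max"]])
    }, character(1)),
    sprintf("separation sweep (%s): %s", sep$criterion,
            paste(sprintf("t=%g -> %.1f%%", bundle$sweep$t,
                          100 * bundle$sweep$fraction_separated),
                  collapse = ", ")),
    sprintf("at t=%g: separated by distance: %d, rescued by characters: %d, unresolved: %d",
            sep$t, sum(per$separated), sum(rescued), sum(unresolved)),
    if (sum(unresolved)) paste("unresolved species:",
                               paste(per$species[unresolved], collapse = ", "))
    else "unresolved: 0"
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run`, `extract`, `distances`, `threshold`,
#' `characters`, `classify`. Arguments are `--key value` pairs; see the
#' package script `inst/cli/v4barcode` for a ready-made launcher. Logs go
#' to stderr; machine-readable outputs only ever go to files.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Integer exit status: 0 ok, 2 usage error, 3 data error.
#' @export
v4_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: v4barcode <simulate|run|extract|distances|threshold|characters|classify> --key value ...")
    2L
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  kv <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--") || i == length(rest)) return(usage())
    kv[[substring(rest[i], 3)]] <- rest[i + 1]
    i <- i + 2
  }
  num <- function(x, d = NULL) if (is.null(x)) d else as.numeric(x)
  tryCatch({
    switch(cmd,
      simulate = {
        p <- synth_params(
          n_species = num(kv$n_species, 20), seqs_per_species = num(kv$seqs, 3),
          ncols = num(kv$ncols, 333), intra_div = num(kv$intra, 0.004),
          inter_div = num(kv$inter, 0.08),
          n_problem_pairs = num(kv$problem_pairs, 0),
          problem_p = num(kv$problem_p, 0.003),
          indel_rate = num(kv$indel_rate, 0.01),
          ambiguity_rate = num(kv$ambiguity_rate, 0.002),
          seed = as.integer(kv$seed %||% stop("--seed required")))
        sim <- generate_alignment(p)
        out <- kv$out %||% "."
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_labeled_fasta(sim$records, file.path(out, "simulated.fasta"))
        utils::write.table(
          sim$records[, c("id", "species", "genus")],
          file.path(out, "simulated_metadata.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        write_truth(sim$truth, file.path(out, "simulated_truth.json"))
        message("wrote simulated.fasta / simulated_metadata.tsv / simulated_truth.json to ", out)
        0L
      },
      run = {
        cfg <- run_config(
          fasta = kv$fasta %||% stop("--fasta required"),
          metadata = kv$metadata, overrides = kv$overrides,
          gap_policy = kv$gap_policy %||% "pairwise",
          thresholds = as.numeric(strsplit(kv$thresholds %||% "0.01,0.02", ",")[[1]]),
          primary_t = num(kv$t, 0.02),
          criterion = kv$criterion %||% "nearest-neighbor",
          cutoff = num(kv$cutoff, 0.004),
          out_dir = kv$out %||% stop("--out required"))
        bundle <- run_pipeline(cfg)
        summarize_run(bundle)
        0L
      },
      extract = {
        rec <- read_labeled_fasta(kv$fasta %||% stop("--fasta required"))
        primers <- if (!is.null(kv$forward)) {
          primer_pair(kv$forward, kv$reverse, num(kv$max_mismatch, 2))
        } else d512_d978()
        amps <- lapply(seq_len(nrow(rec)), function(i)
          extract_amplicon(rec[i, , drop = FALSE], primers))
        ok <- !vapply(amps, is.null, logical(1))
        for (id in rec$id[!ok]) message("no-hit: ", id)
        write_labeled_fasta(do.call(rbind, amps[ok]),
                            kv$out %||% stop("--out required"))
        0L
      },
      distances = {
        rec <- read_labeled_fasta(kv$fasta %||% stop("--fasta required"),
                                  metadata = kv$metadata)
        m <- distance_matrix(rec, gap_policy = kv$gap_policy %||% "pairwise")
        write_distance_matrix(m, kv$out %||% stop("--out required"),
                              format = kv$format %||% "tsv")
        0L
      },
      threshold = {
        rec <- read_labeled_fasta(kv$fasta %||% stop("--fasta required"),
                                  metadata = kv$metadata)
        m <- distance_matrix(rec)
        sw <- threshold_sweep(m, rec,
          grid = as.numeric(strsplit(kv$thresholds %||% "0.01,0.02", ",")[[1]]),
          criterion = kv$criterion %||% "nearest-neighbor")
        utils::write.table(sw, kv$out %||% stop("--out required"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      characters = {
        rec <- read_labeled_fasta(kv$fasta %||% stop("--fasta required"),
                                  metadata = kv$metadata)
        tab <- character_table(rec, max_sites = num(kv$max_sites))
        utils::write.table(as.data.frame(tab),
                           kv$out %||% stop("--out required"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      classify = {
        rec <- read_labeled_fasta(kv$fasta %||% stop("--fasta required"),
                                  metadata = kv$metadata)
        tab <- character_table(rec)
        qry <- read_labeled_fasta(kv$query %||% stop("--query required"))
        out <- data.frame(
          id = qry$id,
          assigned = vapply(qry$residues, function(s)
            paste(classify_sequence(s, tab), collapse = ";"),
            character(1), USE.NAMES = FALSE))
        utils::write.table(out, kv$out %||% stop("--out required"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      usage()
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
}
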