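# seqio: parsing, normalization, overrides, amplicon extraction, trimming,
# deduplication, alignment validation.

write_fasta_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("labelled FASTA parsing fills labels, normalizes and round-trips", {
  f <- write_fasta_lines(c(
    ">id1|Skeletonema marinoi|Skeletonema", "ACGTACGT",
    ">id2|Skeletonema costatum|Skeletonema", "acgtacgu",
    ">id3", "AC.GT-NN"))
  expect_warning(read_labeled_fasta(f), "id3")
  rec <- suppressWarnings(read_labeled_fasta(f))
  expect_equal(rec$id, c("id1", "id2", "id3"))
  expect_equal(rec$species[1:2], c("Skeletonema marinoi", "Skeletonema costatum"))
  expect_equal(rec$genus[1], "Skeletonema")
  expect_equal(rec$residues[2], "ACGTACGT")    # lowercase + U -> T
  expect_equal(rec$residues[3], "AC-GT-NN")    # '.' gap alias
  expect_true(is.na(rec$species[3]))

  # round-trip preserves ids, labels and residues exactly
  out <- withr::local_tempfile(fileext = ".fasta")
  write_labeled_fasta(rec[1:2, ], out)
  back <- read_labeled_fasta(out)
  expect_equal(back[c("id", "species", "genus", "residues")],
               rec[1:2, c("id", "species", "genus", "residues")])
})

test_that("invalid inputs error with the offending record named", {
  f <- write_fasta_lines(c(">dup|a|g", "ACGT", ">dup|b|g", "ACGT"))
  expect_error(read_labeled_fasta(f), "dup")
  expect_error(read_labeled_fasta(tempfile("nope")), "no such file")
  expect_error(seq_records(id = c("x", "y"), species = "s",
                           residues = c("ACGT", "")), "y")
  expect_error(seq_records(id = "x", species = "s", residues = "ACQT"),
               "invalid residue")
})

test_that("metadata side-table overrides header labels", {
  f <- write_fasta_lines(c(">id1|wrong species", "ACGT", ">id2|sp b", "ACGT"))
  meta <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(id = "id1", species = "right species", genus = "Genus"),
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_labeled_fasta(f, metadata = meta)
  expect_equal(rec$species, c("right species", "sp b"))
  expect_equal(rec$genus[1], "Genus")
})

test_that("label overrides relabel matched ids and audit the changes", {
  rec <- seq_records(id = c("AJ810854", "JX437386"),
                     species = c("Thalassiosira anguste-lineata",
                                 "Thalassiosira angulata"),
                     genus = "Thalassiosira",
                     residues = c("ACGT", "ACGT"))
  ov <- data.frame(id = "AJ810854", species = "Thalassiosira angulata")
  res <- apply_overrides(rec, ov)
  expect_equal(res$records$species[1], "Thalassiosira angulata")
  expect_equal(nrow(res$audit), 1)
  expect_equal(res$audit$old, "Thalassiosira anguste-lineata")

  # empty override table is the identity
  ident <- apply_overrides(rec, data.frame())
  expect_equal(ident$records, rec)
  expect_equal(nrow(ident$audit), 0)

  # unknown key guards against typos
  expect_error(apply_overrides(rec, data.frame(id = "XX000000", species = "x")),
               "XX000000")
})

test_that("amplicon extraction returns the inter-primer subsequence", {
  set.seed(7)
  primers <- d512_d978()
  insert <- random_dna(380)
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  template <- paste0(random_dna(100), primers$forward, insert,
                     revcomp(primers$reverse), random_dna(200))
  expect_equal(extract_amplicon(template, primers), insert)

  # one mismatch inside the forward primer is within the default budget
  fwd_mut <- primers$forward
  substr(fwd_mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(fwd_mut, 5, 5))[1]
  template2 <- paste0(random_dna(100), fwd_mut, insert,
                      revcomp(primers$reverse), random_dna(200))
  expect_equal(extract_amplicon(template2, primers), insert)

  # labels ride along on record input
  rec <- seq_records(id = "t1", species = "sp", residues = template)
  amp <- extract_amplicon(rec, primers)
  expect_equal(amp$residues, insert)
  expect_equal(amp$id, "t1")
})

test_that("no primer site within budget gives a no-hit, confirmed by scan", {
  set.seed(11)
  primers <- d512_d978()
  for (rep in 1:5) {
    template <- random_dna(1000)
    fwd_hit <- oracle_primer_hit(template, primers$forward, primers$max_mismatch)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(primers$reverse)))
    rev_hit <- oracle_primer_hit(template, rc, primers$max_mismatch)
    res <- extract_amplicon(template, primers)
    if (is.na(fwd_hit) || is.na(rev_hit)) expect_null(res)
  }
  # an engineered primer-free template is a guaranteed no-hit
  expect_null(extract_amplicon(strrep("A", 1000), primers))
})

test_that("amplicon extraction is position-invariant under prefixes", {
  set.seed(3)
  primers <- primer_pair("ATTCCAGCTCCAATAGCG", "GACTACGATGGTATCTAATC")
  insert <- random_dna(120)
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  core <- paste0(primers$forward, insert, revcomp(primers$reverse),
                 random_dna(50))
  for (k in c(0, 1, 7, 60, 311)) {
    template <- paste0(random_dna(k), core)
    expect_equal(extract_amplicon(template, primers), insert, info = k)
  }
})

test_that("core trimming slices columns and respects bounds", {
  rec <- seq_records(id = c("a", "b"), species = "s",
                     residues = c(random_dna(420), random_dna(420)))
  cut <- trim_to_core(rec, 1, 333)
  expect_equal(alignment_ncols(cut), 333)
  expect_equal(cut$residues, substr(rec$residues, 1, 333))
  # full-width policy is the identity
  expect_equal(trim_to_core(rec, 1, 420)$residues, rec$residues)
  expect_error(trim_to_core(rec, 400, 333), "out of range")
})

test_that("deduplication keeps first representatives, conserves counts", {
  rec <- seq_records(id = c("a", "b", "c", "d"), species = "s",
                     residues = c("ACGT", "ACGA", "ACGT", "AAAA"))
  d <- deduplicate(rec)
  expect_equal(d$records$id, c("a", "b", "d"))
  expect_equal(d$multiplicity, c(a = 2L, b = 1L, d = 1L))
  expect_equal(sum(d$multiplicity), nrow(rec))

  all_same <- seq_records(id = letters[1:5], species = "s",
                          residues = rep("ACGT", 5))
  d2 <- deduplicate(all_same)
  expect_equal(nrow(d2$records), 1)
  expect_equal(unname(d2$multiplicity), 5L)

  distinct <- seq_records(id = c("a", "b"), species = "s",
                          residues = c("ACGT", "ACGA"))
  expect_equal(deduplicate(distinct)$records, distinct)
})

test_that("alignment validation reports anomalies and errors on ragged input", {
  ragged <- seq_records(id = c("a", "bad"), species = "s",
                        residues = c("ACGT", "ACGTA"))
  expect_error(validate_alignment(ragged), "bad")

  gappy <- seq_records(id = c("a", "b"), species = "s",
                       residues = c("AC-GN", "AC-GA"))
  expect_warning(validate_alignment(gappy), "3")
  report <- suppressWarnings(validate_alignment(gappy))
  expect_equal(report$all_gap_columns, 3L)
  expect_equal(report$ambiguity, c(a = 1L))

  clean <- seq_records(id = c("a", "b"), species = "s",
                       residues = c("ACGT", "ACGA"))
  rep2 <- validate_alignment(clean)
  expect_length(rep2$all_gap_columns, 0)
  expect_length(rep2$ambiguity, 0)
})
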