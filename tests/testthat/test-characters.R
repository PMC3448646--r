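# characters: variable sites, pure/compound/private diagnostics, guide
# tree, classification.

aln_from <- function(strings, species = NULL) {
  n <- length(strings)
  if (is.null(species)) species <- names(strings)
  seq_records(id = sprintf("q%02d", seq_len(n)), species = species,
              genus = "G", residues = unname(strings))
}

test_that("variable sites index polymorphic columns with ordinals", {
  same <- aln_from(rep("ACGTACGT", 3), species = c("A", "A", "B"))
  expect_equal(nrow(variable_sites(same)), 0)

  rec <- aln_from(c("ACGTA", "ACCTA", "ACGTA"), species = c("A", "B", "C"))
  vs <- variable_sites(rec)
  expect_equal(vs$column, 3)
  expect_equal(vs$ordinal, 1)

  # gap-only variation ignored by default, counted on request
  gapped <- aln_from(c("AC-TA", "ACCTA"), species = c("A", "B"))
  expect_equal(nrow(variable_sites(gapped)), 0)
  expect_equal(variable_sites(gapped, gap_as_state = TRUE)$column, 3)

  set.seed(13)
  for (i in 1:10) {
    rec <- random_grouped_records(sample(5:12, 1), sample(30:60, 1))
    expect_equal(variable_sites(rec)$column,
                 oracle_variable_cols(seq_matrix_of(rec)))
  }
})

test_that("pure diagnostics require a state unique to the whole group", {
  # group A all 'T' at the variable site, all others 'C'
  rec <- aln_from(c("ATGG", "ATGG", "ACGG", "ACGG"),
                  species = c("A", "A", "B", "C"))
  d <- find_pure_diagnostics(rec)
  dA <- d[d$group == "A", ]
  expect_equal(dA$columns, "2")
  expect_equal(dA$states, "T")
  expect_equal(dA$kind, "pure")

  # two groups with identical sequences: no pure diagnostic for either
  twin <- aln_from(c("ACGT", "ACGT", "AGGT"),
                   species = c("pseudocostatum", "tropicum", "other"))
  d2 <- find_pure_diagnostics(twin)
  expect_false(any(d2$group %in% c("pseudocostatum", "tropicum")))

  # a member gap or ambiguity at the site disqualifies it for the group
  gap <- aln_from(c("ATGG", "A-GG", "ACGG"), species = c("A", "A", "B"))
  expect_equal(nrow(find_pure_diagnostics(gap)[
    find_pure_diagnostics(gap)$group == "A", ]), 0)

  # a non-member ambiguity overlapping the state disqualifies too:
  # Y expands to {C, T} and so can carry the T
  amb <- aln_from(c("ATGG", "ATGG", "AYGG"), species = c("A", "A", "B"))
  expect_false("2" %in% find_pure_diagnostics(amb)$columns[
    find_pure_diagnostics(amb)$group == "A"])
})

test_that("compound diagnostics are minimal joint patterns", {
  # site 2 'A' and site 4 'G' each shared with outsiders, never jointly
  rec <- aln_from(c(
    "TATG", "TATG",   # group A: joint (2:A, 4:G)
    "TACC",           # B carries 2:A without 4:G
    "TGTG",           # C carries 4:G without 2:A
    "TGCC"),
    species = c("A", "A", "B", "C", "D"))
  d <- find_compound_diagnostics(rec, order = 2)
  dA <- d[d$group == "A", ]
  expect_true(any(dA$columns == "2,4" & dA$states == "A,G"))
  # neither site is pure for A
  expect_false(any(find_pure_diagnostics(rec)$group == "A" &
                     find_pure_diagnostics(rec)$columns %in% c("2", "4")))

  # the CC-CT situation: two close species differ only by a joint pattern
  # at consecutive variable sites
  cym <- aln_from(c(
    "ACCA", "ACCA",   # Plagiogrammopsis: CC at sites 2,3
    "ACTA", "ACTA",   # Brockmanniella: CT at sites 2,3
    "ATTA", "GCCA"),  # outsiders sharing each single state
    species = c("P", "P", "B", "B", "o1", "o2"))
  dc <- find_compound_diagnostics(cym, order = 2)
  expect_true(any(dc$group == "B" & dc$columns == "2,3" & dc$states == "C,T"))

  # budget cap errors loudly instead of truncating
  set.seed(17)
  big <- random_grouped_records(10, 50)
  expect_error(find_compound_diagnostics(big, order = 2, max_sites = 3),
               "budget")
})

test_that("diagnostic searches match exhaustive enumeration (orders 1-3)", {
  set.seed(23)
  for (i in 1:15) {
    rec <- random_grouped_records(sample(6:12, 1), sample(20:40, 1),
                                  sub_rate = 0.06)
    mat <- seq_matrix_of(rec)
    oracle <- oracle_diagnostics(mat, rec$species, orders = 1:3)
    got <- rbind(
      find_pure_diagnostics(rec),
      find_compound_diagnostics(rec, order = 2),
      find_compound_diagnostics(rec, order = 3))
    expect_equal(diag_keys(got[c("group", "kind", "columns", "states")]),
                 diag_keys(oracle))
  }
})

test_that("private characters match brute force and exclude shared states", {
  rec <- aln_from(c("ACGT", "AGGT", "AGGT", "TGGT"),
                  species = c("A", "A", "B", "B"))
  # q01's C at column 2 is unique to it within group A
  d <- find_private_characters(rec)
  expect_true(any(d$group == "A" & d$columns == "2" & d$states == "C"))
  # the T at column 1 is shared between a B member and no one else: private
  # for B; the G at column 2 is shared across groups: not private
  expect_false(any(d$states == "G" & d$columns == "2"))

  set.seed(29)
  for (i in 1:10) {
    rec <- random_grouped_records(sample(6:10, 1), sample(20:40, 1))
    mat <- seq_matrix_of(rec)
    o <- oracle_private(mat, rec$species)
    g <- find_private_characters(rec)
    expect_equal(sort(paste(g$group, g$columns, g$states)),
                 sort(paste(o$group, o$columns, o$states)))
  }
})

test_that("NJ guide tree recovers additive topologies deterministically", {
  # additive distances from the unrooted tree ((A:1,B:2):1,(C:3,D:4));
  # scaled into p-distance range
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0) / 30, 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  m <- structure(list(ids = c("A", "B", "C", "D"), p = d), class = "p_dist")
  tree <- build_guide_tree(m)
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(truth)), 0,
               ignore_attr = TRUE)

  # 3 taxa: closed-form star branch lengths
  d3 <- matrix(c(0, .10, .16, .10, 0, .18, .16, .18, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m3 <- structure(list(ids = c("x", "y", "z"), p = d3), class = "p_dist")
  t3 <- build_guide_tree(m3)
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["x"]], (.10 + .16 - .18) / 2)
  expect_equal(bl[["y"]], (.10 + .18 - .16) / 2)
  expect_equal(bl[["z"]], (.16 + .18 - .10) / 2)

  # deterministic under ties
  set.seed(31)
  rec <- random_grouped_records(8, 60)
  m8 <- distance_matrix(rec)
  expect_identical(ape::write.tree(build_guide_tree(m8)),
                   ape::write.tree(build_guide_tree(m8)))
  expect_error(build_guide_tree(structure(list(ids = "a", p = matrix(0)),
                                          class = "p_dist")), "at least 3")
})

test_that("classification follows the diagnostic rule-sets", {
  rec <- aln_from(c("ATGG", "ATGG", "ACGG", "AAGG"),
                  species = c("A", "A", "B", "C"))
  tab <- character_table(rec)
  expect_equal(classify_sequence("ATGG", tab), "A", ignore_attr = TRUE)
  # with a pure diagnostic per group, every clean training sequence
  # classifies to exactly its own group
  for (i in seq_len(nrow(rec))) {
    got <- classify_sequence(rec$residues[i], tab)
    expect_equal(got, rec$species[i], ignore_attr = TRUE, info = i)
  }
  expect_error(classify_sequence("ATG", tab), "length")

  # two groups sharing one rule-set: ambiguous two-group assignment
  shared <- structure(data.frame(
    group = c("X", "Y"), kind = "pure", ordinals = "1",
    columns = "2", states = "T", stringsAsFactors = FALSE),
    ncols = 4, class = c("character_table", "data.frame"))
  expect_setequal(classify_sequence("ATGG", shared), c("X", "Y"))
  # no rule satisfied: unassigned
  expect_length(classify_sequence("AGGG", shared), 0)
})

test_that("classification accuracy on synthetic queries meets planted truth", {
  plan <- list(
    list(group = "sp01", kind = "pure", columns = 5L, states = "T"),
    list(group = "sp02", kind = "pure", columns = 15L, states = "G"),
    list(group = "sp03", kind = "compound_pure", columns = c(25L, 35L),
         states = c("A", "C")))
  sim <- generate_alignment(synth_params(
    n_species = 6, seqs_per_species = 5, ncols = 120, intra_div = 0.002,
    inter_div = 0.03, planted_characters = plan, indel_rate = 0,
    ambiguity_rate = 0, seed = 77))
  tab <- character_table(sim$records, orders = 1:2)
  hits <- 0; total <- 0
  for (g in c("sp01", "sp02", "sp03")) {
    for (s in sim$records$residues[sim$records$species == g]) {
      total <- total + 1
      hits <- hits + (identical(as.character(classify_sequence(s, tab)), g))
    }
  }
  expect_equal(hits, total)  # planted diagnostics guarantee self-assignment
})

test_that("tree-derived grouping covers all ids with k groups", {
  set.seed(37)
  rec <- random_grouped_records(10, 60)
  m <- distance_matrix(rec)
  grp <- tree_grouping(m, k = 3)
  expect_setequal(names(grp), rec$id)
  expect_equal(length(unique(grp)), 3)
  d <- find_pure_diagnostics(rec, grouping = grp)
  expect_true(all(d$group %in% grp))
})
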