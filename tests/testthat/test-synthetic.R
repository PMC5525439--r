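test_that("community generator respects length, GC and determinism", {
  spec <- community_spec(
    genomes = data.frame(id = "g1", length = 10000, gc = 0.5, n_contigs = 1),
    seed = 1)
  com <- gen_community(spec)
  s <- com$sequences[["g1"]]
  expect_equal(nchar(s), 10000)
  gc <- lengths(regmatches(s, gregexpr("[GC]", s)))
  expect_lt(abs(gc - 5000), 3 * sqrt(10000 * 0.25))
  com2 <- gen_community(spec)
  expect_identical(com$sequences, com2$sequences)

  d1 <- file.path(tempdir(), "com1"); d2 <- file.path(tempdir(), "com2")
  gen_community(spec, out = d1); gen_community(spec, out = d2)
  expect_identical(readBin(file.path(d1, "g1.fasta"), "raw", 1e6),
                   readBin(file.path(d2, "g1.fasta"), "raw", 1e6))
})

test_that("relatives hit their target ANI", {
  # identity case first
  com0 <- gen_community(community_spec(
    genomes = data.frame(id = "p", length = 2000, gc = 0.5, n_contigs = 1),
    relatives = data.frame(parent = "p", id = "c", ani = 1.0, indel_rate = 0),
    seed = 2))
  expect_identical(com0$sequences[["c"]], com0$sequences[["p"]])

  # alignment-measured ANI within ±0.01 of target (independent aligner)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (a in c(0.80, 0.85, 0.95)) {
    com <- gen_community(community_spec(
      genomes = data.frame(id = "p", length = 3000, gc = 0.5, n_contigs = 1),
      relatives = data.frame(parent = "p", id = "c", ani = a,
                             indel_rate = 0.002),
      seed = round(1000 * a)))
    expect_lt(abs(com$truth$realized_identity - a), 0.01)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(com$sequences[["p"]]),
      Biostrings::DNAString(com$sequences[["c"]]),
      substitutionMatrix = sm, gapOpening = 0, gapExtension = 2,
      type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ani_meas <- sum(p == s & p != "-") / length(p)
    expect_lt(abs(ani_meas - a), 0.01)
  }
})

test_that("excessive indel burden is rejected", {
  spec <- community_spec(
    genomes = data.frame(id = "p", length = 1000, gc = 0.5, n_contigs = 1),
    relatives = data.frame(parent = "p", id = "c", ani = 0.9,
                           indel_rate = 0.08),
    seed = 1)
  expect_error(gen_community(spec), "net length change")
})

test_that("spec validation rejects invalid communities", {
  g <- data.frame(id = "g", length = 100, gc = 0.5, n_contigs = 1)
  expect_error(community_spec(g[, -2]), "columns")
  expect_error(community_spec(transform(g, length = 0)), "> 0")
  expect_error(community_spec(transform(g, gc = 1)), "gc")
  expect_error(community_spec(g, relatives = data.frame(
    parent = "g", ani = 0.5, indel_rate = 0)), "ANI")
  expect_error(community_spec(g, rrna_operons = data.frame(
    genome = "g", start = 50, end = 200)), "bounds")
})

test_that("simulated reads recover the target identity", {
  com <- gen_community(community_spec(
    genomes = data.frame(id = "g", length = 20000, gc = 0.5, n_contigs = 1),
    seed = 4))
  # p = 1: every read is an exact substring (either strand)
  rs1 <- sim_reads(com, read_sim_spec("g", n_reads = 25, identity = 1,
                                      indel_frac = 0, seed = 5))
  g <- com$sequences[["g"]]
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  for (r in rs1$reads)
    expect_true(grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE))
  expect_true(all(rs1$truth$identity == 1))

  # truth-table mean identity within ±0.005 at n = 1000, mean length 100
  rs2 <- sim_reads(com, read_sim_spec("g", n_reads = 1000,
                                      length_mean = 100, length_sd = 10,
                                      identity = 0.90, seed = 6))
  expect_equal(nrow(rs2$truth), 1000)
  expect_lt(abs(mean(rs2$truth$identity) - 0.90), 0.005)
  expect_true(all(rs2$truth$end > rs2$truth$start))
  expect_true(all(rs2$truth$identity >= 0 & rs2$truth$identity <= 1))

  # determinism
  rs3 <- sim_reads(com, read_sim_spec("g", n_reads = 50, seed = 7))
  rs4 <- sim_reads(com, read_sim_spec("g", n_reads = 50, seed = 7))
  expect_identical(rs3$reads, rs4$reads)

  expect_error(sim_reads("", read_sim_spec("g", n_reads = 1)), "empty")
})

test_that("rRNA truth flags mark reads overlapping the operon", {
  com <- make_test_community(
    rrna = data.frame(genome = "gA", start = 5000, end = 10000))
  rs <- sim_reads(com, read_sim_spec("gA", n_reads = 100, identity = 1,
                                     indel_frac = 0, seed = 8))
  ov <- rs$truth$overlaps_rrna
  by_hand <- rs$truth$start < 10000 & rs$truth$end > 5000
  expect_identical(ov, by_hand)
  expect_true(any(ov) && any(!ov))
})

test_that("marker families carry exactly the declared polymorphic sites", {
  fam0 <- gen_marker_family(12, 800, 0, seed = 1)
  cen0 <- haplotype_census(fam0)
  expect_equal(cen0$n_haplotypes, 1)
  expect_true(cen0$all_identical)

  fam <- gen_marker_family(10, 500, 3, seed = 2)
  # brute-force column scan over all pairwise comparisons
  mat <- do.call(rbind, strsplit(unname(fam$sequences), ""))
  union_pos <- sort(unique(unlist(lapply(1:9, function(i)
    lapply((i + 1):10, function(j) which(mat[i, ] != mat[j, ]))))))
  expect_identical(union_pos, sort(fam$truth$position))
  expect_equal(length(union_pos), 3)

  fam1 <- gen_marker_family(1, 300, 0, seed = 3)
  expect_equal(haplotype_census(fam1)$n_haplotypes, 1)

  expect_error(gen_marker_family(5, 10, 11, seed = 1), "<= length")
  expect_identical(gen_marker_family(6, 400, 2, seed = 9)$sequences,
                   gen_marker_family(6, 400, 2, seed = 9)$sequences)
})

test_that("synthetic proteorhodopsins carry the declared key residues", {
  for (res in c("M", "Q", "A")) {
    p <- gen_pr_protein(res, seed = 3)
    f <- attr(p, "features")
    ch <- strsplit(unname(p), "")[[1]]
    expect_identical(ch[f[["proton_acceptor"]]], "D")
    expect_identical(ch[f[["proton_donor"]]], "E")
    expect_identical(ch[f[["retinal_lysine"]]], "K")
    expect_identical(ch[f[["tuning"]]], res)
  }
  expect_error(gen_pr_protein("Z"), "amino-acid")
  expect_identical(gen_pr_protein("M", seed = 4), gen_pr_protein("M", seed = 4))
})
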