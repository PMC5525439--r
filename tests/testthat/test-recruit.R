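mk_hits <- function(pident, evalue, qcov, qlen = 100,
                    qseqid = paste0("r", seq_along(pident)),
                    sseqid = "gA", bitscore = 100, sstart = 1) {
  n <- length(pident)
  span <- round(qcov * qlen)
  data.frame(qseqid = rep_len(qseqid, n), sseqid = rep_len(sseqid, n),
             pident = pident, length = span, mismatch = 0, gapopen = 0,
             qstart = 1, qend = span,
             sstart = rep_len(sstart, n),
             send = rep_len(sstart, n) + span - 1,
             evalue = rep_len(evalue, n),
             bitscore = rep_len(bitscore, n), qlen = qlen)
}

test_that("threshold filter applies the three strict predicates", {
  # boundaries: identity strictly above 70, coverage >= 0.90 inclusive
  h <- mk_hits(pident = c(69.9, 70.1, 70), evalue = 1e-8, qcov = 0.95)
  expect_equal(filter_hits(h)$pident, 70.1)
  h2 <- mk_hits(pident = 96, evalue = 1e-8, qcov = 0.89)
  expect_equal(nrow(filter_hits(h2)), 0)
  h3 <- mk_hits(pident = 96, evalue = 1e-8, qcov = 0.90)
  expect_equal(nrow(filter_hits(h3)), 1)
  h4 <- mk_hits(pident = 96, evalue = 1e-6, qcov = 0.95)   # e-value strict
  expect_equal(nrow(filter_hits(h4)), 0)

  # the five-hit toy table: exactly hits 1 and 5 survive
  toy <- rbind(mk_hits(96, 1e-7, 0.95), mk_hits(96, 1e-5, 0.95),
               mk_hits(65, 1e-7, 0.95), mk_hits(96, 1e-7, 0.80),
               mk_hits(71, 1e-8, 0.90))
  toy$qseqid <- paste0("r", 1:5)
  surv <- filter_hits(toy)
  expect_equal(surv$qseqid, c("r1", "r5"))

  expect_error(filter_hits(transform(toy, qlen = NA)), "qlen")
})

test_that("filter agrees with brute-force predicate enumeration", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 200
    h <- mk_hits(pident = runif(n, 50, 100),
                 evalue = 10^runif(n, -12, -3),
                 qcov = 1)
    h$qstart <- 1
    h$qend <- sample(80:100, n, replace = TRUE)
    keep <- mapply(function(e, p, qs, qe, ql)
      e < 1e-6 && p > 70 && (abs(qe - qs) + 1) / ql >= 0.9,
      h$evalue, h$pident, h$qstart, h$qend, h$qlen)
    expect_equal(filter_hits(h)$qseqid, h$qseqid[keep])
  }
})

test_that("within-genome dedup keeps the best hit deterministically", {
  h <- mk_hits(pident = c(90, 92, 92), evalue = 1e-8, qcov = 0.95,
               qseqid = "r1")
  h$bitscore <- c(80, 95, 95)
  h$length <- c(60, 60, 70)
  d <- dedup_within_genome(h)
  expect_equal(nrow(d), 1)
  expect_equal(d$bitscore, 95)
  expect_equal(d$length, 70)                 # tie broken by aln_len

  # equal bitscore and length: smaller subject start wins
  h2 <- mk_hits(pident = 90, evalue = 1e-8, qcov = 0.95, qseqid = "r1")
  h2 <- rbind(h2, h2)
  h2$sstart <- c(500, 100); h2$send <- c(589, 189)
  expect_equal(dedup_within_genome(h2)$sstart, 100)

  # hits to different genomes are kept (dedup is within genome)
  h3 <- rbind(mk_hits(90, 1e-8, 0.95, qseqid = "r1", sseqid = "gA"),
              mk_hits(90, 1e-8, 0.95, qseqid = "r1", sseqid = "gB"))
  expect_equal(nrow(dedup_within_genome(h3)), 2)
})

test_that("dedup output count equals distinct (read, genome) pairs", {
  set.seed(31)
  n <- 1000
  h <- mk_hits(pident = runif(n, 70, 100), evalue = 1e-8, qcov = 0.95,
               qseqid = sample(paste0("r", 1:60), n, replace = TRUE),
               sseqid = sample(c("gA", "gB", "gC"), n, replace = TRUE))
  h$bitscore <- runif(n, 50, 200)
  d <- dedup_within_genome(h)
  expect_equal(nrow(d), nrow(unique(h[, c("qseqid", "sseqid")])))
})

test_that("ribosomal masking removes overlapping hits, half-open", {
  db <- build_db(list(gA = c(gA_c1 = strrep("ACGT", 2000))),
                 masks = data.frame(chrom = "gA", start = c(250, 100),
                                    end = c(5250, 200)))
  # [110, 260) overlaps [250, 5250) by 10 bp -> removed
  h1 <- mk_hits(96, 1e-8, 0.95, sstart = 111)  # subject 111..260 1-based
  h1$send <- 260; h1$length <- 150
  expect_equal(nrow(mask_ribosomal(h1, db)), 0)
  # [0, 100) touches mask [100, 200) only at the boundary -> kept
  h2 <- mk_hits(96, 1e-8, 1, qlen = 100, sstart = 1)
  h2$send <- 100
  expect_equal(nrow(mask_ribosomal(h2, db)), 1)
})

test_that("masked removal matches synthetic truth flags", {
  com <- make_test_community(
    rrna = data.frame(genome = "gA", start = 5000, end = 10000))
  db <- build_db(com)
  rs <- sim_reads(com, read_sim_spec("gA", n_reads = 150, identity = 1,
                                     indel_frac = 0, seed = 12))
  h <- local_align(rs$reads, db, best_per_genome = TRUE)
  hA <- h[h$sseqid == "gA", ]
  kept <- mask_ribosomal(hA, db)
  removed <- setdiff(hA$qseqid, kept$qseqid)
  flagged <- rs$truth$read[rs$truth$overlaps_rrna]
  expect_setequal(removed, flagged)
})

test_that("competitive assignment picks the best genome with fixed ties", {
  h <- rbind(mk_hits(95, 1e-9, 0.95, qseqid = "r1", sseqid = "gA"),
             mk_hits(90, 1e-9, 0.95, qseqid = "r1", sseqid = "gB"))
  h$bitscore <- c(200, 150)
  r <- competitive_assign(h)
  expect_equal(nrow(r), 1)
  expect_equal(r$genome, "gA")

  # full tie -> lexicographically smaller genome id
  h2 <- rbind(mk_hits(95, 1e-9, 0.95, qseqid = "r1", sseqid = "gB"),
              mk_hits(95, 1e-9, 0.95, qseqid = "r1", sseqid = "gA"))
  expect_equal(competitive_assign(h2)$genome, "gA")

  # coordinates become 0-based half-open, strand-normalized
  h3 <- mk_hits(95, 1e-9, 0.95, qseqid = "r1")
  h3$sstart <- 260; h3$send <- 111
  r3 <- competitive_assign(h3)
  expect_equal(c(r3$start, r3$end), c(110, 260))
})

test_that("cascade conserves reads and filters commute", {
  # Commutation dedup(filter(h)) == filter(dedup(h)) holds when, within
  # each (read, genome) group, passing the filter is monotone in dedup's
  # bitscore ranking.  Aligner output has that shape: e-value is a
  # decreasing function of bitscore at fixed qlen, and a read's identity
  # and coverage on one genome vary far less than its bitscore rank.  The
  # generator below reproduces that regime (group-level pident/coverage,
  # e-value derived from bitscore); adversarial tables that give a group's
  # top-bitscore hit a worse identity than a lower-ranked hit genuinely
  # break commutation and are excluded by construction.
  set.seed(55)
  n <- 600
  key <- data.frame(qseqid = sample(paste0("r", 1:80), n, replace = TRUE),
                    sseqid = sample(c("gA", "gB"), n, replace = TRUE))
  grp <- paste(key$qseqid, key$sseqid)
  g_pid <- setNames(runif(length(unique(grp)), 60, 100), unique(grp))
  g_qe <- setNames(sample(85:100, length(unique(grp)), TRUE), unique(grp))
  h <- mk_hits(pident = unname(g_pid[grp]), evalue = 1, qcov = 1,
               qseqid = key$qseqid, sseqid = key$sseqid)
  h$qend <- unname(g_qe[grp])
  h$bitscore <- runif(n, 30, 70)   # spans the e-value threshold at ~46.5
  h$evalue <- score_to_evalue(h$bitscore, h$qlen, 1e6)
  rec <- competitive_assign(dedup_within_genome(filter_hits(h)))
  expect_lte(nrow(rec), length(unique(h$qseqid)))
  expect_false(any(duplicated(rec$qseqid)))

  # dedup and filter commute
  a <- filter_hits(dedup_within_genome(h))
  b <- dedup_within_genome(filter_hits(h))
  expect_equal(a[order(a$qseqid, a$sseqid), ],
               b[order(b$qseqid, b$sseqid), ], ignore_attr = TRUE)

  # masking commutes with the per-hit filter on any input
  db <- build_db(list(gA = c(gA_c1 = strrep("ACGT", 500)),
                      gB = c(gB_c1 = strrep("ACGT", 500))),
                 masks = data.frame(chrom = "gA", start = 0, end = 300))
  h2 <- h[h$send <= 2000, ]
  m1 <- mask_ribosomal(filter_hits(h2), db)
  m2 <- filter_hits(mask_ribosomal(h2, db))
  expect_equal(m1[order(m1$qseqid, m1$sseqid), ],
               m2[order(m2$qseqid, m2$sseqid), ], ignore_attr = TRUE)
})

test_that("tightening any threshold never increases survivors", {
  set.seed(56)
  n <- 400
  h <- mk_hits(pident = runif(n, 60, 100), evalue = 10^runif(n, -10, -4),
               qcov = 1)
  h$qend <- sample(85:100, n, replace = TRUE)
  base <- nrow(filter_hits(h))
  for (p in list(filter_params(min_pident = 80),
                 filter_params(max_evalue = 1e-8),
                 filter_params(min_qcov = 0.95)))
    expect_lte(nrow(filter_hits(h, p)), base)
})

test_that("reads from a known genome recruit back to it", {
  com <- make_test_community()
  db <- build_db(com)
  rs <- sim_reads(com, read_sim_spec("gA", n_reads = 150, identity = 0.98,
                                     seed = 33))
  rec <- recruit(local_align(rs$reads, db), db)
  expect_gte(mean(rec$genome == "gA"), 0.99)
  expect_lt(abs(mean(rec$pident) - 98), 1)
})
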