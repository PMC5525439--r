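# Independent full Smith-Waterman oracle (score only), linear gap costs.
# Row-vectorized: horizontal gap recursion solved with a running cummax.
sw_oracle <- function(read, subj, match = 1, mismatch = -2, gap = -2.5) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  s <- strsplit(subj, "", fixed = TRUE)[[1]]
  n <- length(s)
  j <- seq_len(n)
  prev <- numeric(n + 1)
  best <- 0
  for (i in seq_along(r)) {
    sub <- ifelse(s == r[i], match, mismatch)
    t <- pmax(0, prev[j] + sub, prev[j + 1] + gap)
    cur <- gap * j + cummax(t - gap * j)
    best <- max(best, cur)
    prev <- c(0, cur)
  }
  best
}

oracle_bitscore <- function(score, lambda = 1.28, K = 0.46) {
  (lambda * score - log(K)) / log(2)
}

# genome-derived read with at most 3 edits per 50 bp, so a clean 11-mer
# stretch always exists (pigeonhole) and seeding cannot miss
rand_oracle_instance <- function(read_len = 50, genome_len = 500,
                                 n_sub = 2, n_indel = 0) {
  bases <- c("A", "C", "G", "T")
  g <- paste(sample(bases, genome_len, replace = TRUE), collapse = "")
  st <- sample.int(genome_len - read_len + 1, 1)
  rd <- strsplit(substr(g, st, st + read_len - 1), "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    at <- sample.int(length(rd), n_sub)
    for (p in at) rd[p] <- sample(setdiff(bases, rd[p]), 1)
  }
  if (n_indel > 0) {
    p <- sample(seq(5, length(rd) - 5), 1)
    if (runif(1) < 0.5) rd <- rd[-p]
    else rd <- append(rd, sample(bases, 1), after = p)
  }
  list(read = paste(rd, collapse = ""), genome = g)
}

# brute-force Kyte-Doolittle window means (oracle for predict_tm)
kd_window_oracle <- function(seq, window = 19) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  h <- unname(kd[s]); h[is.na(h)] <- 0
  half <- (window - 1) / 2
  centers <- seq(half + 1, length(s) - half)
  vapply(centers, function(c) mean(h[(c - half):(c + half)]), numeric(1))
}

# small two-genome community shared by several alignment tests
make_test_community <- function(seed = 11, len = 20000, ani = 0.85,
                                rrna = NULL) {
  gen_community(community_spec(
    genomes = data.frame(id = "gA", length = len, gc = 0.45, n_contigs = 1),
    relatives = data.frame(parent = "gA", id = "gB", ani = ani,
                           indel_rate = 0.002),
    rrna_operons = rrna,
    seed = seed))
}
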