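test_that("genome generation is reproducible and uniform", {
  g1 <- generate_genome(10, seed = 99)
  g2 <- generate_genome(10, seed = 99)
  expect_identical(g1, g2)
  expect_identical(nchar(g1), 10L)
  expect_error(generate_genome(0))
  expect_true(generate_genome(1, seed = 1) %in% c("A", "C", "G", "T"))
  big <- generate_genome(100000, seed = 7)
  freqs <- table(strsplit(big, "")[[1]]) / 100000
  sigma <- sqrt(0.25 * 0.75 / 100000)
  expect_true(all(abs(freqs - 0.25) <= 3 * sigma))
})

test_that("error-free sampling returns exact genome substrings", {
  cfg <- simulation_config(genome_length = 5000, coverage = 3,
                           mean_read_length = 800, sub_rate = 0,
                           ins_rate = 0, del_rate = 0, seed = 13)
  genome <- generate_genome(5000, seed = 13)
  sampled <- sample_reads(genome, cfg)
  for (r in seq_len(nrow(sampled$placements))) {
    pl <- sampled$placements[r, ]
    sub <- substr(genome, pl$start + 1, pl$end)
    got <- sampled$reads$sequences[r]
    expect_identical(got, if (pl$strand == "+") sub else oracle_revcomp(sub))
  }
})

test_that("substitution-only errors hit the configured rate", {
  cfg <- simulation_config(genome_length = 20000, coverage = 5,
                           mean_read_length = 2000, sub_rate = 0.1,
                           ins_rate = 0, del_rate = 0, seed = 14)
  genome <- generate_genome(20000, seed = 14)
  sampled <- sample_reads(genome, cfg)
  expect_identical(sampled$placements$read_length,
                   sampled$placements$end - sampled$placements$start)
  mismatches <- 0; total <- 0
  for (r in seq_len(nrow(sampled$placements))) {
    pl <- sampled$placements[r, ]
    truth <- substr(genome, pl$start + 1, pl$end)
    got <- sampled$reads$sequences[r]
    if (pl$strand == "-") got <- oracle_revcomp(got)
    mismatches <- mismatches +
      sum(strsplit(truth, "")[[1]] != strsplit(got, "")[[1]])
    total <- total + nchar(truth)
  }
  sigma <- sqrt(0.1 * 0.9 / total)
  expect_lt(abs(mismatches / total - 0.1), 3 * sigma)
})

test_that("indel-dominated errors drift read length as expected", {
  cfg <- simulation_config(genome_length = 50000, coverage = 8, seed = 15,
                           mean_read_length = 8000)
  sim <- simulate_reads(cfg)
  ratio <- sum(sim$placements$read_length) /
    sum(sim$placements$end - sim$placements$start)
  # emissions per consumed genome base:
  # ins/(1-ins) + (1-ins-del)/(1-ins) = 1.0459 for 8.6%/4.4%
  expect_lt(abs(ratio - 1.0459), 0.01)
  # total sampled bases track coverage * genome_length
  sampled <- sum(sim$placements$end - sim$placements$start)
  expect_lt(abs(sampled / (8 * 50000) - 1), 0.1)
})

test_that("simulation is byte-reproducible given a seed", {
  cfg <- simulation_config(genome_length = 20000, coverage = 4,
                           mean_read_length = 2000, seed = 77)
  s1 <- simulate_reads(cfg)
  s2 <- simulate_reads(cfg)
  expect_identical(s1$reads$sequences, s2$reads$sequences)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(s1$reads, f1, s1$placements)
  write_fasta(s2$reads, f2, s2$placements)
  write_truth(s1$truth, t1)
  write_truth(s2$truth, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("true overlaps follow half-open interval intersection", {
  pl <- data.frame(id = c("a", "b", "c"),
                   start = c(0, 4000, 100), end = c(5000, 9000, 200),
                   strand = "+", read_length = c(5000, 5000, 100))
  tr <- true_overlaps(pl, min_truth_overlap = 100)
  ab <- tr[tr$id_a == "a" & tr$id_b == "b", ]
  expect_identical(ab$overlap_length, 1000L)
  # touching intervals do not overlap
  pl2 <- data.frame(id = c("a", "b"), start = c(0, 100),
                    end = c(100, 200), strand = "+",
                    read_length = c(100, 100))
  expect_identical(nrow(true_overlaps(pl2, 1)), 0L)
})

test_that("true overlaps equal the brute-force all-pairs intersection", {
  set.seed(501)
  for (trial in 1:10) {
    n <- 10
    start <- sample.int(5000, n)
    len <- sample(200:1500, n, replace = TRUE)
    pl <- data.frame(id = sprintf("r%02d", sample(50, n)), start = start,
                     end = start + len, strand = "+", read_length = len)
    got <- true_overlaps(pl, min_truth_overlap = 100)
    want <- 0L
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      o <- min(pl$end[a], pl$end[b]) - max(pl$start[a], pl$start[b])
      if (o >= 100) {
        want <- want + 1L
        key <- paste(min(pl$id[a], pl$id[b]), max(pl$id[a], pl$id[b]))
        expect_true(key %in% paste(got$id_a, got$id_b))
        expect_identical(got$overlap_length[paste(got$id_a, got$id_b) == key],
                         as.integer(o))
      }
    }
    expect_identical(nrow(got), want)
  }
})

test_that("adjacency marks consecutive sampled reads that overlap", {
  pl <- data.frame(id = c("a", "b", "c"),
                   start = c(0, 1000, 2000), end = c(2500, 3500, 4500),
                   strand = "+", read_length = 2500)
  tr <- true_overlaps(pl, 100)
  expect_identical(nrow(tr), 3L)  # all pairs intersect
  adj <- tr[tr$is_adjacent, ]
  expect_identical(nrow(adj), 2L) # but only a-b and b-c are adjacent
  expect_false(any(adj$id_a == "a" & adj$id_b == "c"))
  # every adjacency pair is an overlap pair by construction
  expect_true(all(tr$is_adjacent %in% c(TRUE, FALSE)))
})

test_that("small irreducible overlaps become rarer as coverage grows", {
  # pool adjacent pairs over replicates: single-run fractions are noisy
  # because adjacent overlaps below half the read length are rare events
  frac_at <- function(cov) {
    small <- 0; total <- 0
    for (rep in 1:3) {
      cfg <- simulation_config(genome_length = 100000, coverage = cov,
                               mean_read_length = 8000,
                               seed = 600 + 10 * rep + cov)
      sim <- simulate_reads(cfg)
      adj <- sim$truth[sim$truth$is_adjacent, ]
      len <- setNames(sim$placements$read_length, sim$placements$id)
      pair_mean <- (len[adj$id_a] + len[adj$id_b]) / 2
      small <- small + sum(adj$overlap_length < 0.5 * pair_mean)
      total <- total + nrow(adj)
    }
    small / total
  }
  fracs <- vapply(c(8, 15, 30), frac_at, 0)
  expect_true(all(fracs >= 0 & fracs <= 1))
  expect_true(all(diff(fracs) < 0))
})

test_that("simulation configs validate rates and geometry", {
  expect_error(simulation_config(sub_rate = 0.5, ins_rate = 0.4,
                                 del_rate = 0.2))
  expect_error(simulation_config(genome_length = 1000,
                                 mean_read_length = 2000))
  expect_error(simulation_config(coverage = 0))
})
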