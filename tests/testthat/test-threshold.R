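two_sample_counts <- function(a, b) {
  dplyr::bind_rows(
    tibble::tibble(sequence = paste0("A", seq_along(a)), sample = "r1",
                   count = as.integer(a)),
    tibble::tibble(sequence = paste0("B", seq_along(b)), sample = "r2",
                   count = as.integer(b))
  )
}

test_that("count distributions expose per-tag counts and a log2 ECDF", {
  tab <- two_sample_counts(c(1, 1, 2, 4), c(8, 8))
  d <- count_distribution(tab, "r1")
  expect_equal(d$counts, c(1L, 1L, 2L, 4L))
  expect_equal(d$ecdf(log2(c(1, 2, 4))), c(0.5, 0.75, 1))
  expect_equal(tidy(d)$ecdf, c(0.5, 0.5, 0.75, 1))

  t2 <- read_count_table(ex_path("table2_extracellular.tsv"))
  d2 <- count_distribution(t2, "extracellular_1")
  expect_length(d2$counts, 20L)
  expect_equal(max(log2(d2$counts)), log2(826))

  expect_error(count_distribution(tab, "nope"), "not present")
})

test_that("the exact KS distance matches hand-derived values", {
  expect_equal(ks_two_sample(c(5, 9, 13), c(5, 9, 13)), 0)
  expect_equal(ks_two_sample(c(1, 1, 1), c(100, 100)), 1)
  # merged-support enumeration: max gap 0.25 for unit-shifted quartets
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("ks_two_sample equals brute force and ks.test on random instances", {
  set.seed(42)
  for (i in 1:50) {
    a <- sample.int(20, sample(2:30, 1), replace = TRUE)
    b <- sample.int(20, sample(2:30, 1), replace = TRUE)
    D <- ks_two_sample(a, b)
    expect_equal(D, oracle_ks(a, b))
    expect_equal(D, ks_two_sample(b, a)) # symmetry
    expect_equal(D, unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  }
})

test_that("D is zero exactly when the two multisets induce the same ECDF", {
  a <- c(1, 1, 2, 5, 5, 9)
  expect_equal(ks_two_sample(a, rep(a, 3)), 0) # same proportions
  set.seed(12)
  for (i in 1:20) {
    b <- sample.int(10, 8, replace = TRUE)
    same <- isTRUE(all.equal(table(factor(a, 1:10)) / length(a),
                             table(factor(b, 1:10)) / length(b),
                             check.attributes = FALSE))
    expect_equal(ks_two_sample(a, b) == 0, same)
  }
})

test_that("identical replicates give a flat zero curve selecting t_min", {
  x <- c(1, 1, 2, 3, 5, 8, 13, 21, 40, 100)
  tab <- two_sample_counts(x, x)
  sw <- adaptive_threshold(tab, "r1", "r2", t_min = 1)
  expect_true(all(sw$sweep$D == 0))
  expect_equal(sw$selected_threshold, 1L)
})

test_that("the sweep curve matches per-threshold recomputation by ks_two_sample", {
  set.seed(5)
  a <- sample.int(60, 120, replace = TRUE)
  b <- sample.int(60, 100, replace = TRUE)
  tab <- two_sample_counts(a, b)
  sw <- adaptive_threshold(tab, "r1", "r2", t_min = 1, t_max = 40)
  cur <- tidy(sw)
  for (t in cur$t) {
    expect_equal(cur$D[cur$t == t], ks_two_sample(a[a >= t], b[b >= t]))
    expect_equal(cur$n_a[cur$t == t], sum(a >= t))
    expect_equal(cur$n_b[cur$t == t], sum(b >= t))
  }
  # retained counts never increase with t
  expect_true(all(diff(cur$n_a) <= 0))
  expect_true(all(diff(cur$n_b) <= 0))
})

test_that("selection is symmetric in the replicates and stable under scaling", {
  spec <- mixture_spec(n_noise_tags = c(800, 200), n_signal_tags = 200)
  tab <- simulate_count_replicates(spec, seed = 9)
  sw_ab <- adaptive_threshold(tab, "rep1", "rep2")
  sw_ba <- adaptive_threshold(tab, "rep2", "rep1")
  expect_equal(sw_ab$selected_threshold, sw_ba$selected_threshold)
  expect_equal(tidy(sw_ab)$D, tidy(sw_ba)$D)

  # doubling all counts maps D(t) onto D(2t): the KS statistic only sees
  # the retained sets, which a common monotone transform leaves unchanged
  tab2 <- dplyr::mutate(tab, count = count * 2L)
  sw2 <- adaptive_threshold(tab2, "rep1", "rep2",
                            t_max = 2L * max(tidy(sw_ab)$t))
  cur <- tidy(sw_ab); cur2 <- tidy(sw2)
  shared_t <- intersect(cur$t, cur2$t[cur2$t %% 2 == 0] / 2)
  expect_equal(cur$D[match(shared_t, cur$t)],
               cur2$D[match(shared_t * 2, cur2$t)])
})

test_that("monotone-decreasing cost curves fall back to the first global min", {
  # constructed so that discordance drains with every threshold step:
  # r1 holds extra mass at every level 1..5, shared tail above
  a <- c(rep(1, 40), rep(2, 30), rep(3, 20), rep(4, 12), rep(5, 6),
         rep(10, 30), rep(20, 30))
  b <- c(rep(10, 30), rep(20, 30))
  tab <- two_sample_counts(a, b)
  sw <- adaptive_threshold(tab, "r1", "r2", t_min = 1, t_max = 15)
  cur <- tidy(sw)
  expect_true(all(diff(cur$D) <= 0))
  expect_equal(sw$selected_threshold, min(cur$t[cur$D == min(cur$D)]))
  expect_equal(sw$selected_threshold, 6L)
})

test_that("degenerate sweeps are refused with clear errors", {
  tab <- two_sample_counts(c(1, 2, 3), c(1, 5))
  expect_error(adaptive_threshold(tab, "r1", "r2", t_min = 3), "fewer than 2")
  expect_error(adaptive_threshold(tab, "r1", "r2", t_min = 1, t_max = 0),
               "t_max")
})

test_that("boundary placement of tiers is lower-inclusive at 32, upper at 10000", {
  tab <- tibble::tibble(
    sequence = paste0("t", 1:4), sample = "s",
    count = c(31L, 32L, 10000L, 10001L)
  )
  tiers <- assign_tiers(tab)
  expect_equal(as.character(tiers$tier), c("Low", "Mid", "Mid", "High"))
})

test_that("the printed tables land in the documented tiers", {
  t1 <- read_count_table(ex_path("table1_intracellular.tsv"))
  tiers1 <- assign_tiers(t1)
  expect_true(all(tiers1$tier == "High"))
  f7 <- tiers1[tiers1$mirna == "hsa-let-7f", ]
  expect_setequal(f7$count, c(1076532L, 667868L))

  t2 <- read_count_table(ex_path("table2_extracellular.tsv"))
  tiers2 <- assign_tiers(t2)
  expect_false(any(tiers2$tier == "High"))
  expect_true(max(tiers2$count) <= 3734)
})

test_that("tier Venn arithmetic counts overlaps per tier", {
  t1 <- read_count_table(ex_path("table1_intracellular.tsv"))
  tiers <- assign_tiers(t1)
  v <- tier_venn(tiers, "intracellular_1", "intracellular_2", "High")
  expect_equal(v$set_a_size, 16L)
  expect_equal(v$set_b_size, 16L)
  expect_equal(v$intersection_size, 16L)

  disj <- assign_tiers(tibble::tibble(
    sequence = c("a", "b"), sample = c("s1", "s2"), count = c(5L, 50000L)))
  expect_equal(tier_venn(disj, "s1", "s2", "Low")$intersection_size, 0L)
  expect_error(tier_venn(tiers, "intracellular_1", "intracellular_2", "Huge"),
               "tier")
})

test_that("cohens_kappa matches hand arithmetic and the contingency oracle", {
  u <- paste0("t", 1:100)
  half <- u[1:50]
  expect_equal(cohens_kappa(half, half, u), 1)
  # |A|=|B|=50, overlap 40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  expect_equal(cohens_kappa(u[1:50], u[c(1:40, 51:60)], u), 0.6)

  # chance-level agreement of random same-size sets
  set.seed(8)
  ks <- replicate(400, cohens_kappa(half, sample(u, 50), u))
  expect_lt(abs(mean(ks)), 0.02)

  expect_error(cohens_kappa(c("x"), half, u), "contained")
})

test_that("kappa equals the exhaustive oracle on every small configuration", {
  for (n in c(1, 2, 3, 5, 8, 12)) {
    u <- paste0("e", seq_len(n))
    for (na in 0:n) for (nb in 0:n) {
      lo <- max(0, na + nb - n)
      for (n11 in lo:min(na, nb)) {
        A <- u[seq_len(na)]
        B <- c(u[seq_len(n11)],
               if (nb > n11) u[(na + 1):(na + nb - n11)])
        expect_equal(cohens_kappa(A, B, u), oracle_kappa(A, B, u),
                     info = paste(n, na, nb, n11))
      }
    }
  }
})

test_that("three-phase summaries report tag counts and mass fractions", {
  tab <- tibble::tibble(sequence = paste0("t", 1:3), sample = "s",
                        count = c(3L, 8L, 20L))
  s <- three_phase_summary(tab, "s", threshold = 32)
  expect_equal(s$mass_fraction[s$phase == "noise"], 1)
  expect_equal(sum(s$mass_fraction), 1)

  t1 <- read_count_table(ex_path("table1_intracellular.tsv"))
  s1 <- three_phase_summary(t1, "intracellular_1")
  expect_equal(s1$n_tags[s1$phase == "high"], 16L)
  expect_equal(s1$mass_fraction[s1$phase == "high"], 1)

  spec <- mixture_spec()
  tab2 <- simulate_count_replicates(spec, seed = 4)
  truth <- attr(tab2, "truth")
  s2 <- three_phase_summary(tab2, "rep1")
  n_noise <- s2$n_tags[s2$phase == "noise"]
  expected <- spec$n_noise_tags[1]
  expect_lt(abs(n_noise - expected), 3 * sqrt(expected) + 1)
})
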