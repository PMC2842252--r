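# Generators: determinism, composition, planting bookkeeping, recovery.

test_that("the same configuration and seed reproduce byte-identical output", {
  cfg <- list(n = 60, plantings = list(planting("TATAAA", -32, 0.3)),
              tract = tc_tract(0.2, units = "TC"))
  a <- sim_promoters(cfg$n, plantings = cfg$plantings, tract = cfg$tract,
                     seed = 91)
  b <- sim_promoters(cfg$n, plantings = cfg$plantings, tract = cfg$tract,
                     seed = 91)
  expect_identical(a$set$seq, b$set$seq)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_promoters(a$set, f1); write_promoters(b$set, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("base composition matches the configuration within binomial error", {
  comp <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  sim <- sim_promoters(1000, utr = 300, comp = comp, seed = 92)
  tab <- table(strsplit(paste(sim$set$seq, collapse = ""), "")[[1]])
  n <- sum(tab)
  for (b in names(comp)) {
    p_hat <- tab[[b]] / n
    expect_lt(abs(p_hat - comp[[b]]), 3 * sqrt(comp[[b]] * (1 - comp[[b]]) / n))
  }
})

test_that("planting bookkeeping: truth rows, fraction 0, collisions reported", {
  sim <- sim_promoters(100, plantings = list(planting("TATAAA", -32, 0)),
                       seed = 93)
  expect_equal(nrow(sim$truth$plantings), 0L)
  sim2 <- sim_promoters(50, plantings = list(planting("CCGGTT", -40, 0.5)),
                        seed = 94)
  expect_equal(nrow(sim2$truth$plantings), 25L)
  for (r in seq_len(5)) {
    id <- sim2$truth$plantings$id[r]
    pos <- sim2$truth$plantings$position[r]
    s <- sim2$set$seq[sim2$set$ids == id]
    i <- pos + sim2$set$upstream + 1
    expect_equal(substr(s, i, i + 5), "CCGGTT")
  }
  # two point plantings at the same spot in the same promoters collide
  expect_warning(
    sim3 <- sim_promoters(20, plantings = list(
      planting("AAAAAA", -32, 1, subset = 1:20),
      planting("CCCCCC", -30, 1, subset = 1:20)), seed = 95),
    "collision")
  expect_equal(nrow(sim3$truth$collisions), 20L)
})

test_that("planted point positions are recovered end to end", {
  hits <- 0
  for (s in 1:10) {
    sim <- sim_promoters(1000, plantings = list(
      planting("TATAAA", -32, 0.2, subset = 1:340),
      planting("CCGGAA", -40, 0.2, subset = 341:680),
      planting("GGTACC", -26, 0.2, subset = 681:1000)), seed = 9100 + s)
    p1 <- detect_plm(sim$set, "TATAAA")$preferential_position
    p2 <- detect_plm(sim$set, "CCGGAA")$preferential_position
    p3 <- detect_plm(sim$set, "GGTACC")$preferential_position
    hits <- hits + (identical(c(p1, p2, p3), c(-32L, -40L, -26L)))
  }
  expect_gte(hits, 9)
})

test_that("expression cloud: determinism, boundary semantics, refit recovery", {
  a <- sim_expression(100, seed = 96)
  b <- sim_expression(100, seed = 96)
  expect_identical(a, b)
  beta <- c(4, 0.1, -2e-3, 1.5e-5)
  se <- sim_expression(10000, coef = beta, noise_sd = 0.8, seed = 97)
  fit <- lm(median_intensity ~ hybridization_pct + I(hybridization_pct^2) +
              I(hybridization_pct^3), data = se$points)
  est <- coef(fit); ses <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est - beta) <= 3 * ses))
  # truth records the generating residual signs
  ec <- classify_expression(se$points)
  agree <- mean(ec$table$HE == (se$truth$sign > 0))
  expect_gt(agree, 0.95)
})

test_that("ortholog counts: degenerate and null calibrations", {
  so <- sim_ortholog_counts(500, 0.4, 1, 0.1, seed = 98)
  expect_equal(so$counts$a, 0L)
  expect_equal(so$counts$c, sum(so$truth$in_a))
  expect_identical(sim_ortholog_counts(300, 0.3, 0.5, 0.2, seed = 99)$counts,
                   sim_ortholog_counts(300, 0.3, 0.5, 0.2, seed = 99)$counts)
  # under the null (independence) the Fisher p is rarely small and the
  # observed conservation tracks the expected one
  calm <- 0
  for (s in 1:100) {
    so <- sim_ortholog_counts(2000, 0.3, 0.25, 0.25, seed = 9900 + s)
    r <- conservation_stats(so$counts)
    if (r$p_value > 0.05) calm <- calm + 1
  }
  expect_gte(calm, 90)
})
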