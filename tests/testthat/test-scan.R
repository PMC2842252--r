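# The detector: positional counts, background fit, SMS, full detection.
# Background-free fixtures use short promoters with a compact scan window.

test_that("positional counts place exact plantings and de-duplicate", {
  cfg <- mini_config()
  up <- 120
  # three promoters with TATAAA first base at -32, w = 1
  seqs <- rep(flat_promoter(170, up, "TATAAA", -32), 3)
  d <- positional_counts(mini_set(seqs, up), "TATAAA", 1, cfg)
  expect_equal(d$values[d$starts == -32], 3L)
  expect_equal(sum(d$values), 3L)

  # one promoter with the motif at -40 and -32: any window covering both
  # counts the promoter once
  s <- flat_promoter(170, up, "TATAAA", -40)
  i <- -32 + up + 1
  substr(s, i, i + 5) <- "TATAAA"
  d10 <- positional_counts(mini_set(s, up), "TATAAA", 10, cfg)
  expect_equal(d10$values[d10$starts == -40], 1L)

  # overlapping occurrences (TCTTCT twice inside TCTTCTTCT) also count once
  s2 <- flat_promoter(170, up, "TCTTCTTCT", -33)
  d2 <- positional_counts(mini_set(s2, up), "TCTTCT", 10, cfg)
  expect_true(all(d2$values <= 1L))
  expect_equal(d2$values[d2$starts == -33], 1L)
})

test_that("counts match the naive per-promoter oracle on random sets", {
  cfg <- mini_config()
  up <- 120
  set.seed(8)
  for (w in c(1, 3, 7)) {
    seqs <- replicate(15, paste(sample(c("A", "C", "T"), 120 + sample(50:80, 1),
                                       TRUE), collapse = ""))
    set <- mini_set(seqs, up)
    d <- positional_counts(set, "CAT", w, cfg)
    expect_equal(d$values,
                 windowed_counts_naive(seqs, up, "CAT", w, -120, 40),
                 label = paste("w =", w))
    expect_true(all(d$values <= d$coverage))
  }
})

test_that("degenerate patterns count a promoter when any expansion matches", {
  cfg <- mini_config()
  up <- 120
  seqs <- c(flat_promoter(170, up, "TATAAA", -30),
            flat_promoter(170, up, "TATATA", -30),
            flat_promoter(170, up))
  d <- positional_counts(mini_set(seqs, up), "TATAWA", 1, cfg)
  expect_equal(d$values[d$starts == -30], 2L)
})

test_that("background fit: constant counts give slope 0 and bound == level", {
  cfg <- mini_config()
  up <- 120
  # every promoter has a C at each position: motif "C" occurs everywhere
  seqs <- rep(strrep("C", 170), 5)
  d <- positional_counts(mini_set(seqs, up), "C", 1, cfg)
  m <- fit_background(d, cfg)
  expect_equal(unname(coef(m)["slope"]), 0)
  expect_equal(unname(coef(m)["intercept"]), 5)
  expect_equal(m$residual_scale, 0)
  expect_equal(predict(m, -80, "upper"), predict(m, -80, "baseline"))
})

test_that("background fit recovers an exact linear trend", {
  d <- structure(list(motif = "X", window_size = 1L, starts = -200:0,
                      values = 7 + 0 * (-200:0), coverage = rep(50L, 201),
                      k = 1L, n_promoters = 50L,
                      learn = c(-200L, -100L), search = c(-100L, 0L)),
                 class = "plm_dist")
  d$values <- 30 + 2 * (d$starts + 200)        # a + b*p exactly
  cfg <- scan_config(learn = c(-200, -100), search = c(-100, 0))
  m <- fit_background(d, cfg)
  expect_equal(unname(coef(m)["slope"]), 2, tolerance = 1e-10)
  expect_equal(unname(coef(m)["intercept"]), 430, tolerance = 1e-8)
  expect_lt(m$residual_scale, 1e-8)
})

test_that("fitted slope is within 3 standard errors of truth for Poisson counts", {
  set.seed(12)
  starts <- -500:-200
  cfg <- scan_config(learn = c(-500, -200), search = c(-200, 100))
  hits <- 0
  for (r in 1:100) {
    lam <- 20 + 0.01 * (starts + 350)
    y <- rpois(length(starts), lam)
    d <- structure(list(motif = "X", window_size = 1L,
                        starts = c(starts, -199:100),
                        values = c(y, integer(300)),
                        coverage = rep(100L, 601), k = 1L, n_promoters = 100L,
                        learn = cfg$learn, search = cfg$search),
                   class = "plm_dist")
    m <- fit_background(d, cfg)
    fit <- lm(y ~ starts)
    se <- summary(fit)$coefficients["starts", "Std. Error"]
    hits <- hits + (abs(coef(m)["slope"] - 0.01) <= 3 * se)
  }
  expect_gte(hits, 95)
})

test_that("SMS is the documented ratio and boundary cases behave", {
  # constructed distribution: peak 40 at p* with baseline 10 and bound 20
  starts <- -200:100
  vals <- rep(10L, length(starts)); vals[starts == -30] <- 40L
  d <- structure(list(motif = "X", window_size = 1L, starts = starts,
                      values = vals, coverage = rep(100L, length(starts)),
                      k = 1L, n_promoters = 100L,
                      learn = c(-200L, -100L), search = c(-100L, 100L)),
                 class = "plm_dist")
  cfg <- scan_config(learn = c(-200, -100), search = c(-100, 100))
  m <- structure(list(intercept = 10, slope = 0, residual_scale = 1,
                      z = 10, gamma = 0, n_learn = 1e9, p_mean = -150,
                      sxx = Inf, ci_level = 0.99, m = 201),
                 class = "plm_background")
  expect_equal(compute_sms(d, m, cfg), 3.0)    # (40-10)/(20-10)

  # peak exactly at the bound -> SMS 1, rejected by the > sms_min rule
  vals2 <- vals; vals2[starts == -30] <- 20L
  d2 <- d; d2$values <- vals2
  expect_equal(compute_sms(d2, m, cfg), 1.0)

  # flat noiseless background: zero denominator is signalled
  m0 <- m; m0$residual_scale <- 0; m0$z <- 10
  expect_error(compute_sms(d, m0, cfg), class = "plm_zero_denominator")
})

test_that("SMS recomputes from the stored record fields", {
  sim <- sim_promoters(600, plantings = list(planting("TATAAA", -32, 0.3)),
                       seed = 21)
  rec <- detect_plm(sim$set, "TATAAA")
  expect_false(is.null(rec))
  expect_equal(rec$sms,
               (rec$peak_count - rec$baseline) / (rec$upper - rec$baseline))
  # and from the raw distribution/model pair
  expect_equal(rec$sms, compute_sms(rec$distribution, rec$model))
})

test_that("detection recovers a planted point position exactly", {
  sim <- sim_promoters(1000, plantings = list(planting("TATAAA", -32, 0.2)),
                       seed = 31)
  rec <- detect_plm(sim$set, "TATAAA")
  expect_false(is.null(rec))
  expect_equal(rec$preferential_position, -32)
  expect_true(rec$preferential_position >= rec$functional_window[1] &&
                rec$preferential_position <= rec$functional_window[2])
  expect_gt(rec$sms, 1)
  expect_setequal(
    intersect(rec$promoter_ids, sim$truth$plantings$id),
    sim$truth$plantings$id)
})

test_that("a uniformly placed motif is almost never called a PLM", {
  fp <- 0
  for (s in 1:100) {
    sim <- sim_promoters(500,
                         plantings = list(planting("GACGTC", 0, 0.2,
                                                   interval = c(-995, 400))),
                         seed = 7000 + s)
    if (!is.null(detect_plm(sim$set, "GACGTC"))) fp <- fp + 1
  }
  expect_lte(fp, 5)
})

test_that("SMS never decreases when the planted fraction grows", {
  sms_of <- function(frac) {
    sim <- sim_promoters(800,
                         plantings = list(planting("TATAAA", -32, frac)),
                         seed = 55)
    rec <- detect_plm(sim$set, "TATAAA")
    if (is.null(rec)) 0 else rec$sms
  }
  s <- vapply(c(0.1, 0.2, 0.4), sms_of, 0)
  expect_true(all(diff(s) >= 0))
})

test_that("translating the planting shifts the preferential position equally", {
  base <- detect_plm(sim_promoters(800,
    plantings = list(planting("CCGGTT", -60, 0.25)), seed = 77)$set, "CCGGTT")
  shifted <- detect_plm(sim_promoters(800,
    plantings = list(planting("CCGGTT", -55, 0.25)), seed = 77)$set, "CCGGTT")
  expect_equal(shifted$preferential_position,
               base$preferential_position + 5)
})

test_that("a masked upstream peak appears after subtracting the masking class", {
  sim <- sim_promoters(1000,
    plantings = list(planting("TATAAA", -32, 1, subset = 1:200),
                     planting("TCTTCT", -33, 1, subset = 201:300)),
    tract = tc_tract(1, subset = 1:200, units = "TCT",
                     n_units = c(8, 12), start = c(5, 60)),
    seed = 2001)
  whole <- detect_plm(sim$set, "TCTTCT")
  expect_false(plm_in_region(whole))           # downstream tract dominates
  expect_gt(whole$preferential_position, 0)
  ta <- detect_plm(sim$set, "TATAWA")
  taless <- subtract_promoters(sim$set, ta$promoter_ids)
  rec <- detect_plm(taless, "TCTTCT")
  expect_true(plm_in_region(rec))
  expect_equal(rec$preferential_position, -33)
})
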