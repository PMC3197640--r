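# compact hand-built experiment: 2 wells, 2-step ladder
toy_experiment <- function(relax = c(100, 110, 70, 80, 50, 60),
                           idr = c(0.1, 0.1, 0.1, 0.1, 0.5, 0.6)) {
  data <- data.frame(
    well_id = rep(c("w1", "w2"), 3),
    condition = rep(c("baseline", "10", "30"), each = 2),
    conc = rep(c(NA, 10, 30), each = 2),
    mean_force_un = 61, frequency_hz = 0.5,
    mean_contraction_velocity = 400,
    mean_relaxation_velocity = relax, idr = idr)
  dose_response_experiment("toy", c(10, 30), data)
}

test_that("baseline normalisation: definition, exactness, idempotence", {
  ex <- toy_experiment()
  norm <- normalize_to_baseline(ex)
  base_rows <- norm$condition == "baseline"
  expect_true(all(norm$mean_relaxation_velocity[base_rows] == 100))
  expect_true(all(norm$mean_force_un[base_rows] == 100))
  # well w1: 70 uN/s against baseline 100 uN/s -> 70%
  expect_equal(norm$mean_relaxation_velocity[norm$well_id == "w1" &
                                               norm$condition == "10"], 70)
  # idempotence
  expect_equal(normalize_to_baseline(norm), norm)
  # zero baseline is flagged undefined, not divided
  ex0 <- toy_experiment()
  ex0$data$mean_force_un[ex0$data$well_id == "w1" &
                           ex0$data$condition == "baseline"] <- 0
  n0 <- normalize_to_baseline(ex0)
  expect_true(all(is.na(n0$mean_force_un[n0$well_id == "w1"])))
  expect_false(anyNA(n0$mean_force_un[n0$well_id == "w2"]))
})

test_that("paired t: frozen example, identity, antisymmetry, degeneracy", {
  b <- c(10, 11, 12, 13)
  t1 <- b + c(-1, -2, -3, -2)
  r <- paired_t_test(b, t1)
  # mean(d) = -2, sd(d) = sqrt(2/3): t = -2 / (0.8165/2) = -4.899
  expect_equal(r$t, -4.898979, tolerance = 1e-6)
  expect_equal(r$p_value, 0.0162766, tolerance = 1e-6)
  ora <- t.test(t1, b, paired = TRUE)
  expect_equal(r$t, unname(ora$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ora$p.value, tolerance = 1e-12)

  expect_equal(paired_t_test(b, b)$p_value, 1)
  flipped <- paired_t_test(t1, b)
  expect_equal(flipped$t, -r$t)
  expect_equal(flipped$p_value, r$p_value)
  deg <- paired_t_test(c(1, 2, 3), c(2, 3, 4))  # constant nonzero shift
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
  expect_error(paired_t_test(1, 2), "n >= 2")
})

test_that("threshold logic on a deterministic toy experiment", {
  ex <- toy_experiment()
  relax <- threshold_concentration(ex, "mean_relaxation_velocity",
                                   procedure = "t", alpha = 0.05)
  # both wells drop by exactly 30 at 10 and 50 at 30: zero-variance
  # differences give the 0-limit p, so the first concentration qualifies
  expect_equal(relax$threshold, 10)
  expect_equal(nrow(relax$table), 2L)
  expect_false(relax$multiplicity_corrected)

  # a paradoxical increase must never be called a decrease threshold
  ex_up <- toy_experiment(relax = c(100, 110, 130, 140, 150, 160))
  up <- threshold_concentration(ex_up, "mean_relaxation_velocity",
                                procedure = "t")
  expect_true(is.na(up$threshold))

  # degenerate alpha accepts the first concentration
  any_alpha <- threshold_concentration(ex, "mean_relaxation_velocity",
                                       procedure = "t", alpha = 1)
  expect_equal(any_alpha$threshold, 10)
})

test_that("simulated drug experiment: threshold at or below the ic50 step", {
  cp <- eht_compound_preset("e4031_like")  # ic50_relax at ladder step 3
  hits <- vapply(1:10, function(s) {
    ex <- simulate_dose_response(cp$model, cp$ladder, n_wells = 4, seed = s)
    th <- threshold_table(ex)
    !is.na(th$threshold_relaxation) &&
      th$threshold_relaxation <= cp$ladder[3]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("weakening a compound never lowers its detected threshold", {
  med_threshold <- function(ic50) {
    m <- drug_effect_model("x", ic50_relax = ic50, scatter_onset = ic50)
    th <- vapply(1:8, function(s) {
      ex <- simulate_dose_response(m, c(1, 3, 10, 30, 100), n_wells = 4,
                                   seed = s)
      t <- threshold_table(ex)$threshold_relaxation
      if (is.na(t)) 1000 else t  # censor "none" above the ladder
    }, numeric(1))
    median(th)
  }
  expect_lte(med_threshold(3), med_threshold(100))
})

test_that("calcium concentration-response table reproduces the curve", {
  ser <- simulate_calcium_series(c(0.2, 1.8, 2.2, 3.0), n_wells = 2,
                                 seed = 2)
  tab <- build_concentration_response(ser)
  expect_equal(tab$conc, c(0.2, 1.8, 2.2, 3.0))
  f <- function(cc) tab$force_mean[tab$conc == cc]
  expect_lt(abs(f(0.2) / f(1.8) - 0.10), 0.03)       # ~90% decrease
  expect_lt(abs(1 - f(2.2) / f(3.0)), 0.05)          # plateau
  one <- build_concentration_response(ser[ser$conc == 1.8, ])
  expect_identical(nrow(one), 1L)
})

test_that("experiment container validates its invariants", {
  ex <- toy_experiment()
  expect_error(dose_response_experiment("x", c(30, 10), ex$data),
               "increasing")
  no_base <- ex$data[ex$data$condition != "baseline" |
                       ex$data$well_id != "w2", ]
  expect_error(dose_response_experiment("x", c(10, 30), no_base),
               "baseline")
})
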