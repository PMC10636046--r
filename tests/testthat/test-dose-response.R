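# fov_metrics + layout fixtures built in code, no images needed
make_fov_table <- function(conditions, n_wells = 3, n_fov = 9,
                           value_fun, nuclei = 40) {
  rows <- list(); lay <- list(); w <- 0
  for (ci in seq_len(nrow(conditions))) {
    for (rep_i in seq_len(n_wells)) {
      w <- w + 1
      wid <- sprintf("W%03d", w)
      lay[[w]] <- data.frame(well_id = wid,
                             compound = conditions$compound[ci],
                             concentration_nM = conditions$concentration_nM[ci],
                             role = conditions$role[ci], replicate = rep_i)
      for (f in seq_len(n_fov))
        rows[[length(rows) + 1]] <- data.frame(
          well_id = wid, fov_id = sprintf("F%02d", f),
          wrapping_index = value_fun(ci, rep_i, f),
          n_nuclei = if (length(nuclei) == 1) nuclei else nuclei[ci])
    }
  }
  list(fov = do.call(rbind, rows), layout = do.call(rbind, lay))
}

nine_point <- 10000 / 3^(0:8)

test_that("aggregation averages over all fields with SEM and a baseline row", {
  conds <- data.frame(compound = c(rep("T3", 2), "vehicle"),
                      concentration_nM = c(100, 10, 0),
                      role = c("reference", "reference", "vehicle"))
  set.seed(1)
  tab <- make_fov_table(conds, n_wells = 3, n_fov = 9,
                        value_fun = function(ci, r, f) c(0.1, 0.05, 0.02)[ci])
  s <- aggregate_conditions(tab$fov, tab$layout)
  t3 <- s[s$compound == "T3", ]
  expect_equal(t3$n_fov, c(27, 27, 27))      # 3 wells x 9 FOV
  expect_equal(t3$concentration_nM, c(100, 10, 0))
  expect_equal(t3$mean_response, c(0.1, 0.05, 0.02))
  expect_equal(t3$sem, c(0, 0, 0))           # identical FOV values
})

test_that("aggregation matches a hand-computed mean and SEM on a toy table", {
  vals <- c(1, 2, 3, 4, 5, 6)
  conds <- data.frame(compound = c("A", "vehicle"),
                      concentration_nM = c(10, 0),
                      role = c("test", "vehicle"))
  k <- 0
  tab <- make_fov_table(conds, n_wells = 2, n_fov = 3,
                        value_fun = function(ci, r, f) {
                          if (ci == 1) vals[(r - 1) * 3 + f] else 0
                        })
  s <- aggregate_conditions(tab$fov, tab$layout)
  a <- s[s$compound == "A" & s$concentration_nM == 10, ]
  expect_equal(a$mean_response, mean(vals))
  expect_equal(a$sem, sd(vals) / sqrt(6))
})

test_that("fields without a layout row are a validation error", {
  conds <- data.frame(compound = "vehicle", concentration_nM = 0,
                      role = "vehicle")
  tab <- make_fov_table(conds, n_wells = 1, n_fov = 2,
                        value_fun = function(...) 0.1)
  orphan <- tab$fov; orphan$well_id[1] <- "W999"
  expect_error(aggregate_conditions(orphan, tab$layout), "layout")
})

test_that("cytotoxic concentrations are excluded from the failing dose upward", {
  mk_series <- function(nuclei) data.frame(
    compound = "A", concentration_nM = c(nine_point, 0), role = "test",
    mean_response = 0.1, sem = 0.01, n_fov = 27,
    nuclei_mean = c(nuclei, 40), included = TRUE)

  s <- exclude_cytotoxic(mk_series(rep(40, 9)))
  expect_true(all(s$included))

  s <- exclude_cytotoxic(mk_series(c(12, rep(40, 8))))  # top dose at 30%
  expect_equal(s$included[s$concentration_nM > 0], c(FALSE, rep(TRUE, 8)))

  s <- exclude_cytotoxic(mk_series(c(10, 15, rep(40, 7))))  # top two doses
  expect_equal(sum(!s$included), 2)
  expect_equal(s$concentration_nM[!s$included], nine_point[1:2])

  # a recovering nuclei count still excludes everything above the first failure
  s <- exclude_cytotoxic(mk_series(c(40, 15, rep(40, 7))))
  expect_equal(s$included[s$concentration_nM > 0],
               c(FALSE, FALSE, rep(TRUE, 7)))
})

test_that("cytotoxicity exclusion flows through from simulated nuclei loss", {
  cfg <- sim_config(fov_shape = c(96L, 96L), n_nuclei = 12L, noise_sd = 0,
                    seed = 31L)
  truths <- list(T3 = dose_response_truth(0.02, 0.1, 30, 1,
                                          concentrations = 1000 / 2^(0:4)))
  loss <- data.frame(compound = "T3",
                     concentration_nM = c(1000, 500),
                     multiplier = c(0.25, 0.3))
  pl <- generate_plate(truths, cfg, reference = "T3", n_wells = 1, n_fov = 2,
                       nuclei_loss = loss)
  res <- run_screen(pl$stacks, pl$layout, reference = "T3")
  excl <- res$series[!res$series$included, ]
  expect_equal(sort(excl$concentration_nM), c(500, 1000))
})

test_that("the 4PL fit recovers noiseless generating parameters", {
  for (ec50 in c(10, 100, 1000)) for (hill in c(0.7, 1, 2)) {
    mu <- fourpl(nine_point, 0.02, 0.12, ec50, hill)
    s <- data.frame(compound = "A", concentration_nM = c(nine_point, 0),
                    role = "test", mean_response = c(mu, 0.02), sem = 0,
                    n_fov = 27, nuclei_mean = 40, included = TRUE)
    f <- fit_4pl(s)
    expect_true(f$converged)
    expect_lt(abs(f$ec50 - ec50) / ec50, 1e-6)
    expect_lt(abs(f$hill - hill), 1e-4)
  }
})

test_that("flat series yield a degenerate fit with undetermined EC50", {
  s <- data.frame(compound = "A", concentration_nM = c(nine_point, 0),
                  role = "test", mean_response = 0.07, sem = 0, n_fov = 27,
                  nuclei_mean = 40, included = TRUE)
  f <- fit_4pl(s)
  expect_false(f$converged)
  chk <- ec50_with_plateau_check(s, f)
  expect_true(is.na(chk$ec50))
  expect_false(chk$plateau_reached)
})

test_that("fewer than four included concentrations cannot be fitted", {
  s <- data.frame(compound = "A", concentration_nM = c(100, 10, 1, 0),
                  role = "test", mean_response = c(0.1, 0.05, 0.03, 0.02),
                  sem = 0, n_fov = 27, nuclei_mean = 40, included = TRUE)
  s$included[1] <- FALSE
  expect_error(fit_4pl(s), ">= 4")
})

test_that("EC50 is undetermined when the response never plateaus", {
  # saturating series: EC50 reported
  mu <- fourpl(nine_point, 0.02, 0.12, 100, 1)
  s <- data.frame(compound = "A", concentration_nM = c(nine_point, 0),
                  role = "test", mean_response = c(mu, 0.02), sem = 0,
                  n_fov = 27, nuclei_mean = 40, included = TRUE)
  chk <- ec50_with_plateau_check(s, fit_4pl(s))
  expect_equal(chk$ec50, 100, tolerance = 1e-5)
  expect_true(chk$plateau_reached)

  # still-rising series: true EC50 far beyond the top tested dose
  mu2 <- fourpl(nine_point, 0.02, 0.12, 50000, 1)
  s2 <- s; s2$mean_response <- c(mu2, 0.02)
  chk2 <- ec50_with_plateau_check(s2, fit_4pl(s2))
  expect_true(is.na(chk2$ec50))
  expect_false(chk2$plateau_reached)
})

test_that("noisy 4PL fits keep the median EC50 error under 10%", {
  # field-level noise at 10% of top, averaged over the assay design of
  # 27 fields of view per condition (3 wells x 9 FOV)
  errs <- vapply(1:200, function(i) {
    tr <- dose_response_truth(0.02, 0.12, 100, 1,
                              replicate_sd = 0.012, n_replicates = 27,
                              seed = 1000 + i)
    ds <- generate_dose_series(tr)
    m <- aggregate(response ~ concentration_nM, ds, mean)
    s <- data.frame(compound = "A",
                    concentration_nM = m$concentration_nM, role = "test",
                    mean_response = m$response, sem = 0, n_fov = 27,
                    nuclei_mean = 40, included = TRUE)
    f <- fit_4pl(s)
    abs(f$ec50 - 100) / 100
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("EC50 bias stays within 5% at 5% noise", {
  est <- vapply(1:200, function(i) {
    tr <- dose_response_truth(0.02, 0.12, 100, 1, replicate_sd = 0.006,
                              n_replicates = 3, seed = 5000 + i)
    ds <- generate_dose_series(tr)
    m <- aggregate(response ~ concentration_nM, ds, mean)
    s <- data.frame(compound = "A",
                    concentration_nM = m$concentration_nM, role = "test",
                    mean_response = m$response, sem = 0, n_fov = 3,
                    nuclei_mean = 40, included = TRUE)
    fit_4pl(s)$ec50
  }, numeric(1))
  gm <- exp(mean(log(est)))
  expect_lt(abs(gm - 100) / 100, 0.05)
})

test_that("efficacy comes from the raw peak and relative efficacy from T3", {
  mk <- function(cp, means, role = "test") data.frame(
    compound = cp, concentration_nM = c(1000, 100, 10, 1, 0), role = role,
    mean_response = c(means, means[4] / 2), sem = 0.01, n_fov = 27,
    nuclei_mean = 40, included = TRUE)
  series <- rbind(mk("T3", c(0.02, 0.05, 0.12, 0.08), "reference"),
                  mk("drugA", c(0.24, 0.2, 0.1, 0.05)))
  res <- efficacy_and_relative(series, reference = "T3")
  t3 <- res[res$compound == "T3", ]
  # peak mid-series, not the top dose
  expect_equal(t3$efficacy, 0.12)
  expect_equal(t3$peak_concentration_nM, 10)
  expect_identical(t3$relative_efficacy, 1)
  expect_equal(res$relative_efficacy[res$compound == "drugA"], 2)
  expect_error(efficacy_and_relative(series, reference = "nope"), "reference")
})

test_that("relative efficacy is invariant to response rescaling", {
  mk <- function(cp, means, role = "test") data.frame(
    compound = cp, concentration_nM = c(1000, 100, 10, 1, 0), role = role,
    mean_response = c(means, 0.01), sem = 0.01, n_fov = 27,
    nuclei_mean = 40, included = TRUE)
  series <- rbind(mk("T3", c(0.1, 0.08, 0.05, 0.02), "reference"),
                  mk("drugA", c(0.15, 0.12, 0.06, 0.02)))
  r1 <- efficacy_and_relative(series, reference = "T3")
  s2 <- series; s2$mean_response <- s2$mean_response * 7; s2$sem <- s2$sem * 7
  r2 <- efficacy_and_relative(s2, reference = "T3")
  expect_equal(r1$relative_efficacy, r2$relative_efficacy)
  expect_equal(r1$relative_efficacy_sem, r2$relative_efficacy_sem)
})

test_that("two-group one-way ANOVA equals the squared-t test", {
  set.seed(77)
  for (i in 1:100) {
    y1 <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    y2 <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    p_aov <- anova_pairwise_p(y1, y2)
    p_t <- t.test(y1, y2, var.equal = TRUE)$p.value
    expect_lt(abs(p_aov - p_t), 1e-10)
  }
})

test_that("compounds are ranked by efficacy with ANOVA-based ties", {
  mkres <- function(cp, eff) data.frame(
    compound = cp, efficacy = eff, efficacy_sem = 0.01,
    peak_concentration_nM = 100, ec50_nM = 10, hill = 1,
    plateau_reached = TRUE, fit_converged = TRUE,
    relative_efficacy = 1, relative_efficacy_sem = 0.1)
  set.seed(42)
  fovr <- rbind(
    data.frame(compound = "A", concentration_nM = 100,
               response = rnorm(27, 10, 1)),
    data.frame(compound = "B", concentration_nM = 100,
               response = rnorm(27, 10.1, 1)),
    data.frame(compound = "C", concentration_nM = 100,
               response = rnorm(27, 5, 1)))
  results <- rbind(mkres("A", 10), mkres("B", 10.1), mkres("C", 5))
  ranked <- rank_compounds(results, fovr)
  expect_equal(ranked$rank[ranked$compound == "B"], 1)
  expect_equal(ranked$rank[ranked$compound == "A"], 1)  # indistinguishable pair ties
  expect_equal(ranked$rank[ranked$compound == "C"], 3)  # competition ranking

  # clearly separated efficacies get distinct ranks
  fovr2 <- do.call(rbind, lapply(1:3, function(k)
    data.frame(compound = LETTERS[k], concentration_nM = 100,
               response = rnorm(27, 10 * k, 0.5))))
  results2 <- rbind(mkres("A", 10), mkres("B", 20), mkres("C", 30))
  ranked2 <- rank_compounds(results2, fovr2)
  expect_equal(ranked2$rank[order(ranked2$compound)], c(3, 2, 1))
})
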