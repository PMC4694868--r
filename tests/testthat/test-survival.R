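sim_surv <- function(n, beta = 0, x = rnorm(n), baseline = 0.1,
                     cens_rate = 0.043) {
  z <- (x - mean(x)) / sd(x)
  t_event <- rexp(n, baseline * exp(beta * z))
  t_cens <- rexp(n, cens_rate)
  list(x = x, time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

test_that("cox_score handles degenerate and permuted inputs", {
  set.seed(71)
  d <- sim_surv(40)
  expect_equal(cox_score(rep(3, 40), d$time, d$event), 0)  # constant covariate
  s <- cox_score(d$x, d$time, d$event)
  perm <- sample(40)
  expect_equal(cox_score(d$x[perm], d$time[perm], d$event[perm]), s,
               tolerance = 1e-12)
  expect_equal(cox_score(-d$x, d$time, d$event), -s, tolerance = 1e-12)
  expect_error(cox_score(d$x, d$time, rep(0, 40)), "no events")
})

test_that("cox_score matches the double-loop oracle and the coxph score test", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    d <- sim_surv(n, beta = runif(1, -0.5, 0.5))
    # force some ties to exercise Breslow handling
    d$time <- round(d$time, 1) + 0.1
    s <- cox_score(d$x, d$time, d$event)
    expect_equal(s, bf_cox_score(d$x, d$time, d$event), tolerance = 1e-10)
    fit <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                           ties = "breslow")
    expect_equal(s^2, summary(fit)$sctest[["test"]], tolerance = 1e-6)
  }
})

test_that("positive score means higher expression, higher hazard", {
  set.seed(73)
  d <- sim_surv(300, beta = 1)
  expect_gt(cox_score(d$x, d$time, d$event), 2)
  dp <- sim_surv(300, beta = -1)
  expect_lt(cox_score(dp$x, dp$time, dp$event), -2)
})

test_that("select_genes_by_cox ranks by |score| and keeps both signs", {
  set.seed(74)
  n <- 200
  expr <- matrix(rnorm(n * 30), n, dimnames = list(NULL, sprintf("g%02d", 1:30)))
  d <- sim_surv(n)
  z_haz <- scale(expr[, "g01"]); z_pro <- scale(expr[, "g02"])
  t_event <- rexp(n, 0.1 * exp(0.9 * z_haz - 0.9 * z_pro))
  coh <- cohort(expr, pmax(pmin(t_event, rexp(n, 0.043)), 1e-6),
                as.integer(t_event <= rexp(n, 0.043)))
  sel <- select_genes_by_cox(coh, cutoff = 2.39)
  expect_true(all(abs(sel$score) >= 2.39))
  expect_true(all(c("g01", "g02") %in% sel$gene_id))
  expect_gt(sel$score[sel$gene_id == "g01"], 0)
  expect_lt(sel$score[sel$gene_id == "g02"], 0)
  expect_equal(sel$gene_id[1:2], sel$gene_id[order(-abs(sel$score))][1:2])
  all_ranked <- select_genes_by_cox(coh, cutoff = 0)
  expect_equal(nrow(all_ranked), 30)
  expect_equal(attr(select_genes_by_cox(coh, c("g01", "nope")), "not_evaluated"),
               "nope")
})

test_that("median split sends ties to the low group", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_error(median_split(rep(5, 4)), "degenerate")
  set.seed(75)
  x <- rnorm(31)
  expect_equal(sum(median_split(x) == "low"), 16)  # (n+1)/2 for distinct odd n
})

test_that("KM estimate matches the hand fixture and the product-limit oracle", {
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0))
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$survival, c(4 / 5, 3 / 5, 3 / 10))
  expect_equal(km$at_risk, c(5, 4, 2))

  all_cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0)
  expect_equal(km_survival_at(all_cens, 100), 1)

  set.seed(76)
  for (rep in 1:10) {
    d <- sim_surv(sample(10:80, 1))
    d$time <- round(d$time, 1) + 0.1
    got <- km_estimate(d$time, d$event)
    ref <- bf_km(d$time, d$event)
    expect_equal(got$time, ref$time)
    expect_equal(got$survival, ref$survival, tolerance = 1e-12)
    expect_equal(got$at_risk, ref$at_risk)
    expect_equal(got$events, ref$events)
    # time-scale invariance
    sc <- km_estimate(d$time * 3.5, d$event)
    expect_equal(sc$time, got$time * 3.5)
    expect_equal(sc$survival, got$survival, tolerance = 1e-12)
  }
})

test_that("log-rank statistic matches the hypergeometric oracle", {
  # identical survival in both groups -> statistic 0
  t0 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e0 <- c(1, 0, 1, 0, 1, 0, 1, 0)
  g0 <- rep(c("a", "b"), each = 4)
  same <- logrank_test(t0, e0, g0)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$pvalue, 1, tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    d <- sim_surv(n)
    d$time <- round(d$time, 1) + 0.1
    g <- sample(c("a", "b"), n, TRUE)
    if (length(unique(g)) < 2) next
    got <- logrank_test(d$time, d$event, g)
    expect_equal(got$statistic, bf_logrank_chisq(d$time, d$event, g),
                 tolerance = 1e-10)
    expect_equal(got$pvalue, pchisq(got$statistic, 1, lower.tail = FALSE))
    # label-swap invariance
    swapped <- logrank_test(d$time, d$event, ifelse(g == "a", "b", "a"))
    expect_equal(swapped$statistic, got$statistic, tolerance = 1e-10)
  }
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two non-empty")
})

test_that("2-means risk groups recover separated clusters and orient by survival", {
  set.seed(78)
  n <- 60
  truth <- rep(c(0, 1), each = n / 2)
  expr <- cbind(g1 = rnorm(n, truth * 6), g2 = rnorm(n, truth * 6))
  # cluster 1 (truth == 1) gets much worse survival
  t_event <- rexp(n, 0.05 * exp(2.5 * truth))
  grp <- kmeans2_risk_groups(expr, pmax(t_event, 1e-6), rep(1, n), seed = 9)
  expect_equal(unname(table(grp)["high_risk"]), sum(truth == 1))
  expect_true(all((grp == "high_risk") == (truth == 1)))
  # determinism under the same seed
  expect_equal(kmeans2_risk_groups(expr, pmax(t_event, 1e-6), rep(1, n), seed = 9),
               grp)
  # single-gene panel: assignment is a threshold between the cluster means
  x1 <- matrix(c(rnorm(30, 0), rnorm(30, 4)), ncol = 1,
               dimnames = list(NULL, "g"))
  g1 <- kmeans2_risk_groups(x1, pmax(rexp(60, 0.05 * exp(2 * (x1 > 2))), 1e-6),
                            rep(1, 60), seed = 3)
  ord <- order(x1[, 1])
  expect_equal(length(unique(diff(as.integer(g1[ord])))), 2)  # one switch point
  expect_error(kmeans2_risk_groups(matrix(1, 4, 2), 1:4, rep(1, 4)),
               "degenerate")
})

test_that("subgroup excludes unknown statuses on constrained axes", {
  set.seed(79)
  expr <- matrix(rnorm(12), 6, dimnames = list(sprintf("p%d", 1:6),
                                               c("g1", "g2")))
  coh <- cohort(expr, time = 1:6, event = rep(1, 6),
                er_status = c("positive", "positive", "negative", "positive",
                              "negative", "positive"),
                her2_status = c("unknown", "positive", "negative", "negative",
                                "unknown", "positive"))
  both <- subgroup(coh, er = "positive", her2 = "positive")
  expect_setequal(both$patient_ids, c("p2", "p6"))   # p1 unknown HER2 excluded
  expect_equal(subgroup(coh)$patient_ids, coh$patient_ids)  # any/any identity
  expect_warning(subgroup(subset_coh <- subgroup(coh, er = "negative"),
                          her2 = "positive"), "empty")
})

test_that("simulated receptor prevalences are recovered by subgroup counts", {
  cfg <- sim_config(seed = 5, cohort_n = 570)
  sc <- simulate_cohort(cfg, sprintf("G%04d", 1:50))
  counts <- sc$truth$her2_counts
  coh <- sc$cohort
  er_pos <- subgroup(coh, er = "positive")
  expect_equal(length(er_pos$patient_ids), sc$truth$er_positive)
  expect_equal(length(subgroup(coh, her2 = "positive")$patient_ids),
               unname(counts["positive"]))
  # proportions near the configured prevalences (Binomial, n = 570)
  expect_lt(abs(mean(coh$er_status == "positive") - 0.73), 0.06)
  expect_lt(abs(mean(coh$her2_status == "unknown") - 0.288), 0.06)
})

test_that("single-gene KM is deterministic and directionally correct", {
  set.seed(80)
  n <- 400
  expr <- matrix(rnorm(n * 5), n, dimnames = list(NULL, sprintf("g%d", 1:5)))
  z <- scale(expr[, "g1"])
  t_event <- rexp(n, 0.1 * exp(-0.5 * z))    # protective gene
  t_cens <- rexp(n, 0.043)
  coh <- cohort(expr, pmax(pmin(t_event, t_cens), 1e-6),
                as.integer(t_event <= t_cens))
  r1 <- single_gene_km(coh, "g1")
  r2 <- single_gene_km(coh, "g1")
  expect_identical(r1$statistic, r2$statistic)   # no randomness on this path
  expect_lt(r1$pvalue, 0.05)
  t_med <- median(coh$time)
  expect_gt(km_survival_at(r1$curves$high, t_med),
            km_survival_at(r1$curves$low, t_med))
  expect_error(single_gene_km(coh, "nope"), "not in cohort")
})
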