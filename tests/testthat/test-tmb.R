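test_that("TMB counts non-silent SNVs per sample and is additive", {
  v <- make_variants(n = 6, sample_id = "P1",
                     variant_classification = c("Missense_Mutation",
                                                "Missense_Mutation",
                                                "Missense_Mutation", "Silent",
                                                "Silent", "Nonsense_Mutation"))
  expect_equal(unname(compute_tmb(v)), 4L)
  expect_equal(unname(compute_tmb(
    make_variants(n = 2, variant_classification = "Silent"))), 0L)
  expect_equal(unname(compute_tmb(v[0, ], sample_ids = "P1")), 0L)
  # additivity over disjoint variant sets
  expect_equal(compute_tmb(v), compute_tmb(v[1:3, ]) + compute_tmb(v[4:6, ]))
})

test_that("median and percentile splits follow the tie conventions", {
  tmb <- setNames(c(1, 2, 3, 4), paste0("S", 1:4))
  g <- median_split(tmb)
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_warning(g_eq <- median_split(setNames(rep(5, 3), paste0("S", 1:3))),
                 "all TMB")
  expect_true(all(g_eq == "high"))
  # a sample exactly at the median is high
  g_odd <- median_split(setNames(c(1, 2, 3), paste0("S", 1:3)))
  expect_equal(as.character(g_odd), c("low", "high", "high"))

  tmb20 <- setNames(1:20, sprintf("S%02d", 1:20))
  g3 <- percentile_split(tmb20, top_fraction = 0.10)
  expect_equal(sum(g3 == "very_high"), 2)
  expect_equal(sum(g3 == "high"), 9)
  expect_equal(sum(g3 == "low"), 9)
  # top_fraction = 0 reduces to the median split
  g0 <- percentile_split(tmb20, top_fraction = 0)
  expect_equal(as.character(g0), as.character(median_split(tmb20)))
  # threshold sweep between the 40th and 60th percentile runs cleanly
  for (tf in seq(0.4, 0.6, by = 0.05)) {
    gs <- percentile_split(tmb20, top_fraction = tf)
    expect_equal(sum(table(gs)), 20)
  }
  # grouping is invariant to sample order
  perm <- sample(20)
  expect_equal(as.character(percentile_split(tmb20[perm], 0.10)),
               as.character(g3[perm]))
})

test_that("the logrank statistic matches an explicit risk-table computation", {
  clin <- data.frame(sample_id = paste0("S", 1:6),
                     os_time = c(1, 2, 3, 4, 5, 6),
                     os_event = c(1, 1, 1, 0, 0, 1))
  groups <- setNames(factor(rep(c("low", "high"), 3),
                            levels = c("low", "high")), clin$sample_id)
  got <- logrank_test(groups, clin)

  # independent oracle: observed minus expected events over the risk table
  o1 <- e1 <- v1 <- 0
  for (t in sort(unique(clin$os_time[clin$os_event == 1]))) {
    at_risk <- clin$os_time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == "low")
    d <- sum(clin$os_time == t & clin$os_event == 1)
    d1 <- sum(clin$os_time == t & clin$os_event == 1 & groups == "low")
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(got$chisq, (o1 - e1)^2 / v1, tolerance = 1e-9)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq((o1 - e1)^2 / v1, 1, lower.tail = FALSE))
})

test_that("identical survival in both groups gives a null logrank result", {
  clin <- data.frame(sample_id = paste0("S", 1:8),
                     os_time = rep(c(2, 4, 6, 8), 2),
                     os_event = rep(c(1, 1, 0, 1), 2))
  groups <- setNames(rep(c("low", "high"), each = 4), clin$sample_id)
  got <- logrank_test(groups, clin)
  expect_equal(got$chisq, 0, tolerance = 1e-9)
  expect_equal(got$p, 1, tolerance = 1e-9)
  expect_error(logrank_test(setNames(rep("low", 8), clin$sample_id), clin),
               "2 nonempty groups")
})

test_that("the Kaplan-Meier estimator matches the closed-form product limit", {
  clin <- data.frame(sample_id = paste0("S", 1:6),
                     os_time = c(3, 5, 7, 7, 9, 11),
                     os_event = c(1, 0, 1, 1, 0, 1))
  fit <- km_fit(setNames(rep("all", 6), clin$sample_id), clin)
  # hand product-limit: t=3: 5/6; t=7: (5/6)(2/4); t=11: (5/6)(2/4)(0/1)
  expect_equal(summary(fit, times = c(3, 7, 11))$surv,
               c(5 / 6, 5 / 6 * 2 / 4, 0), tolerance = 1e-12)
})

test_that("the Cox fit maximizes an independently coded partial likelihood", {
  set.seed(31)
  n <- 40
  tmb <- setNames(sample(1:200, n, replace = TRUE), sprintf("C%02d", 1:n))
  clin <- data.frame(sample_id = names(tmb),
                     age = round(rnorm(n, 60, 8), 1),
                     stage = sample(c("I", "II", "III", "IV"), n, TRUE))
  x <- cbind(log10(tmb + 1), clin$age,
             c(I = 1, II = 2, III = 3, IV = 4)[clin$stage])
  beta_true <- c(-0.8, 0.03, 0.3)
  haz <- exp(drop(x %*% beta_true)) / 500
  clin$os_time <- round(rexp(n, haz), 3)
  clin$os_event <- as.integer(runif(n) < 0.8)
  res <- cox_tmb(clin, tmb)
  expect_equal(res$status, "ok")
  beta_hat <- log(res$coefficients$hr)

  # hand-coded partial log-likelihood (no ties by construction)
  npll <- function(beta) {
    lp <- drop(x %*% beta)
    ll <- 0
    for (i in which(clin$os_event == 1)) {
      risk <- clin$os_time >= clin$os_time[i]
      ll <- ll + lp[i] - log(sum(exp(lp[risk])))
    }
    -ll
  }
  opt <- optim(c(0, 0, 0), npll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(beta_hat, opt$par, tolerance = 1e-4)
  # the fitted coefficients sit at a stationary point of the oracle
  eps <- 1e-5
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- eps
    grad_j <- (npll(beta_hat + e) - npll(beta_hat - e)) / (2 * eps)
    expect_lt(abs(grad_j), 1e-3)
  }
  # Wald CI brackets the HR point estimate
  expect_true(all(res$coefficients$ci_lower <= res$coefficients$hr &
                    res$coefficients$hr <= res$coefficients$ci_upper))
})

test_that("unknown stages are excluded and degenerate fits are flagged", {
  set.seed(8)
  n <- 30
  tmb <- setNames(sample(1:50, n, TRUE), sprintf("D%02d", 1:n))
  clin <- data.frame(sample_id = names(tmb), age = rnorm(n, 60, 5),
                     stage = c(rep("II", n - 3), rep("unknown", 3)),
                     os_time = rexp(n, 1 / 500),
                     os_event = rbinom(n, 1, 0.7))
  # all known stages identical -> singular stage column -> flagged, not crash
  expect_message(res <- suppressWarnings(cox_tmb(clin, tmb)), "excluded 3")
  expect_true(res$status %in% c("ok", "failed"))
})
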