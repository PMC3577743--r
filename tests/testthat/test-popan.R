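test_that("POPAN likelihood equals the exhaustive path-sum oracle", {
  # deterministic toy: certain detection, single entry occasion
  ch_sure <- matrix(1L, 5, 2)
  expect_equal(popan_loglik(ch_sure, 1, 1, c(1, 0), 5), 0)
  # random small instances, 2 and 3 occasions, vs brute-force enumeration
  set.seed(31)
  for (rep in 1:20) {
    T <- sample(2:3, 1)
    phi <- runif(T - 1, 0.4, 0.95)
    p <- runif(T, 0.3, 0.9)
    pent <- as.vector(rmultinom(1, 20, rep(1, T))) / 20
    ch <- simulate_popan_histories(30, phi, p, pent)
    if (nrow(ch) < 2) next
    N <- nrow(ch) + sample(0:10, 1)
    expect_equal(popan_loglik(ch, phi, p, pent, N),
                 oracle_popan_loglik(ch, phi, p, pent, N),
                 tolerance = 1e-10)
  }
  # impossible N
  expect_identical(popan_loglik(ch_sure, 0.9, 0.8, c(0.5, 0.5), 3), -Inf)
})

test_that("likelihood profiles peak near the empirical detection fraction", {
  set.seed(5)
  ch <- simulate_popan_histories(60, 1, c(0.7, 0.7, 0.7), c(1, 0, 0))
  p_emp <- mean(colMeans(ch))
  lls <- vapply(seq(0.2, 0.95, by = 0.05), function(pp)
    popan_loglik(ch, 1, pp, c(1, 0, 0), 60), numeric(1))
  p_best <- seq(0.2, 0.95, by = 0.05)[which.max(lls)]
  expect_lt(abs(p_best - p_emp), 0.075)
})

test_that("model structures carry the standard parameter counts", {
  T <- 6L
  labels <- c("phi(t)p(.)pent(.)N" = 8L, "phi(.)p(t)pent(.)N" = 9L,
              "phi(.)p(.)pent(.)N" = 4L, "phi(t)p(.)pent(t)N" = 12L,
              "phi(.)p(.)pent(t)N" = 8L, "phi(t)p(t)pent(t)N" = 17L)
  models <- parse_popan_models(paste(names(labels), collapse = ","))
  K <- vapply(models, coastcete:::popan_K, integer(1), T = T)
  expect_equal(unname(K), unname(labels))
  expect_equal(vapply(models, `[[`, character(1), "label"), names(labels))
})

test_that("fitting recovers parameters and is invariant to row order", {
  set.seed(101)
  ch <- simulate_popan_histories(150, 0.9, 0.8, c(0.5, rep(0.1, 5)))
  fit <- fit_popan(ch, popan_model("constant", "constant", "constant"),
                   n_starts = 5, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$phi[1], 0.9, tolerance = 0.08)
  expect_equal(fit$p[1], 0.8, tolerance = 0.08)
  expect_gte(fit$N_m, nrow(ch))
  # permuted rows give identical estimates
  perm <- sample(nrow(ch))
  fit2 <- fit_popan(ch[perm, ], popan_model("constant", "constant", "constant"),
                    n_starts = 5, seed = 1)
  expect_equal(fit2$N_m, fit$N_m, tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
  # certain detection pins the superpopulation at the observed count
  set.seed(8)
  ch_p1 <- simulate_popan_histories(50, 0.9, 1, c(0.5, 0.25, 0.25))
  fit_p1 <- fit_popan(ch_p1, popan_model("constant", "constant", "constant"),
                      n_starts = 5, seed = 2)
  expect_equal(fit_p1$N_m, nrow(ch_p1), tolerance = 0.01)
})

test_that("QAICc arithmetic, AICc reduction and penalty monotonicity", {
  expect_equal(qaicc(-100, 4, 1.4, 77), 200 / 1.4 + 8 + 40 / 72)
  expect_equal(qaicc(-100, 4, 1, 77),
               -2 * -100 + 2 * 4 + 2 * 4 * 5 / (77 - 4 - 1))
  expect_error(qaicc(-100, 4, 0.8, 77), "chat")
  expect_error(qaicc(-100, 10, 1, 11), "sample size")
  # inflating chat can only move the ranking toward smaller-K models
  fits <- list(a = list(ll = -90, K = 9), b = list(ll = -100, K = 4))
  rank_at <- function(chat) {
    q <- vapply(fits, function(f) qaicc(f$ll, f$K, chat, 77), numeric(1))
    names(sort(q))
  }
  expect_equal(rank_at(1)[1], "a")     # big model wins without inflation
  expect_equal(rank_at(3)[1], "b")     # heavy inflation favors fewer params
})

test_that("bootstrap chat is about 1 for well-specified data and floored at 1", {
  # the deviance ratio for a single dataset is noisy; average a few
  set.seed(71)
  chats <- vapply(1:3, function(s) {
    ch <- simulate_popan_histories(90, 0.9, 0.75, c(0.6, rep(0.08, 5)))
    fit <- fit_popan(ch, popan_model("constant", "constant", "constant"),
                     n_starts = 3, seed = s)
    as.numeric(estimate_chat(ch, fit, n_boot = 25, seed = s + 100))
  }, numeric(1))
  expect_true(all(chats >= 1))           # floored at 1 by construction
  expect_lte(mean(chats), 1.2)           # consistent with no overdispersion
})

test_that("individual heterogeneity inflates chat above 1", {
  set.seed(73)
  # two-class detection mixture: half the animals nearly certain, half weak
  sim_mix <- function() {
    ch_hi <- simulate_popan_histories(45, 0.95, 0.95, c(0.6, rep(0.08, 5)))
    ch_lo <- simulate_popan_histories(45, 0.95, 0.25, c(0.6, rep(0.08, 5)))
    rbind(ch_hi, ch_lo)
  }
  hits <- 0L
  for (s in 1:2) {
    ch <- sim_mix()
    fit <- fit_popan(ch, popan_model("constant", "constant", "constant"),
                     n_starts = 4, seed = s)
    chat <- estimate_chat(ch, fit, n_boot = 30, seed = s + 10)
    if (chat > 1) hits <- hits + 1L
  }
  expect_gte(hits, 1L)
})

test_that("mark-ratio totals reproduce the published conversions", {
  all_years <- total_abundance(81, 2.5, 0.77, 77)
  expect_equal(all_years$N_rounded, 105)
  y2006 <- total_abundance(59, 6.4, 0.74, 31)
  expect_equal(y2006$N_rounded, 80)
  # theta = 1 collapses to the marked estimate and its variance
  t1 <- total_abundance(81, 2.5, 1, 77)
  expect_equal(t1$N, 81)
  expect_equal(t1$se, 2.5)
  expect_equal(t1$cv, t1$se / t1$N)
  expect_error(total_abundance(81, 2.5, 0, 77), "theta")
})

test_that("model ranking table is sorted and respects a fixed chat", {
  set.seed(41)
  ch <- simulate_popan_histories(80, 0.9, c(0.55, 0.66, 0.86, 0.86, 0.86, 0.92),
                                 c(0.75, rep(0.05, 5)))
  ms <- rank_popan_models(ch, "phi(.)p(t)pent(.)N, phi(.)p(.)pent(.)N",
                          chat = 1.4, seed = 6)
  expect_equal(ms$chat, 1.4)
  expect_equal(ms$table$qaicc, sort(ms$table$qaicc))
  expect_setequal(ms$table$K, c(9L, 4L))
  for (f in ms$fits)
    expect_equal(f$loglik,
                 popan_loglik(ch, f$phi, f$p, f$pent, f$N_m),
                 tolerance = 1e-8)
})
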