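# AASE calling, landscape bookkeeping, progression screen, SF ranking

toy_events <- function(psi, groups, types = NULL, genes = NULL) {
  E <- nrow(psi)
  info <- data.frame(event_id = rownames(psi),
                     type = types %||% rep("SE", E),
                     gene = genes %||% paste0("gene", seq_len(E)),
                     stringsAsFactors = FALSE)
  structure(list(info = info, psi = psi,
                 groups = setNames(groups, colnames(psi))),
            class = "splice_event_table")
}

test_that("boundary events are never called aberrant", {
  set.seed(1)
  n <- 20
  groups <- rep(c("tumor", "control"), each = n)
  # event 1: delta 0.04 with tiny noise (q will be tiny); event 2: big delta
  # diluted by many null events so its q exceeds 0.01
  psi <- rbind(
    ev_smalldelta = c(rep(0.54, n), rep(0.50, n)) + rnorm(2 * n, 0, 0.002),
    ev_bigdelta = pmin(pmax(c(rnorm(n, 0.65, 0.28), rnorm(n, 0.35, 0.28)),
                            0), 1),
    matrix(runif(48 * 2 * n), 48, 2 * n,
           dimnames = list(paste0("null", 1:48), NULL)))
  colnames(psi) <- paste0("s", 1:(2 * n))
  calls <- call_aase(toy_events(psi, groups))
  sm <- calls[calls$event_id == "ev_smalldelta", ]
  expect_lt(abs(sm$delta_inclevel), 0.05)
  expect_lt(sm$adj_p, 0.01)       # highly significant ...
  expect_false(sm$passes)         # ... but the delta gate fails it
  # a delta > 0.05 with q >= 0.01 must not pass either
  bg <- calls[calls$event_id == "ev_bigdelta", ]
  if (bg$adj_p >= 0.01) expect_false(bg$passes)
  expect_true(all(calls$passes == (!calls$skipped &
                                     abs(calls$delta_inclevel) > 0.05 &
                                     calls$adj_p < 0.01)))
})

test_that("events with < 3 observed IncLevels per group are skipped", {
  psi <- rbind(ok = runif(8), sparse = c(0.1, NA, NA, NA, 0.9, 0.8, 0.7, 0.2))
  colnames(psi) <- paste0("s", 1:8)
  calls <- call_aase(toy_events(psi, rep(c("tumor", "control"), each = 4)))
  expect_true(calls$skipped[calls$event_id == "sparse"])
  expect_match(calls$skip_reason[calls$event_id == "sparse"], "non-missing")
  expect_false(calls$skipped[calls$event_id == "ok"])
  expect_error(call_aase(toy_events(psi, rep("tumor", 8))), "control")
})

test_that("flipping inclusion negates delta but leaves calls unchanged", {
  sim <- simulate_cohort(small_config(seed = 17, n_per_group = 12))
  c1 <- call_aase(sim$events)
  flipped <- sim$events
  flipped$psi <- 1 - flipped$psi
  c2 <- call_aase(flipped)
  expect_equal(c1$delta_inclevel, -c2$delta_inclevel, tolerance = 1e-12)
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
  expect_identical(c1$passes, c2$passes)
})

test_that("landscape_summary is exact bookkeeping over passing calls", {
  psi <- matrix(runif(6 * 8), 6, 8,
                dimnames = list(paste0("e", 1:6), paste0("s", 1:8)))
  ev <- toy_events(psi, rep(c("tumor", "control"), each = 4),
                   types = c("SE", "SE", "MX", "RI", "A3", "A5"),
                   genes = c("gA", "gB", "gA", "gC", "gB", "gB"))
  calls <- call_aase(ev)
  calls$passes <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)  # fixed scenario
  s <- landscape_summary(calls)
  # gA: SE+MX; gB: SE+A5; gC: none passing
  expect_equal(s$n_genes, 2L)
  expect_equal(s$genes_single_type, 0L)
  expect_equal(unname(s$events_per_type[c("SE", "MX", "A5")]), c(2L, 1L, 1L))
  expect_equal(s$type_intersections["MX", "SE"], 1L)  # gA
  expect_equal(s$type_intersections["SE", "SE"], 2L)
  # independent recount from the calls table
  hits <- calls[calls$passes, ]
  recount <- length(unique(hits$gene))
  expect_equal(s$n_genes, recount)
})

test_that("progression screen flags planted hazard events and rejects constants", {
  sim <- simulate_cohort(small_config(seed = 23, n_per_group = 40,
                                      hazard_event_beta = 12,
                                      censor_rate = 0.1))
  calls <- call_aase(sim$events)
  prog <- progression_aase(calls, sim$events, sim$cohort$meta, "PFS")
  hz <- sim$truth$events$event_id[sim$truth$events$hazard_beta > 0]
  got <- prog[prog$event_id %in% hz, ]
  expect_gte(mean(got$significant), 0.5)
  expect_true(all(got$beta > 0))
  # null calibration: non-hazard passing events ~5% significant
  null_sig <- prog$significant[!(prog$event_id %in% hz)]
  expect_lt(mean(null_sig), 0.3)
})

test_that("a coupled regulator dominates the SF correlation ranking", {
  sim <- simulate_cohort(small_config(seed = 29, n_per_group = 20,
                                      n_events = 40, n_aberrant = 10,
                                      n_coupled_events = 20,
                                      sf_coupling = 0.85))
  prot <- imputed_protein(sim)
  calls <- call_aase(sim$events)
  rk <- sf_correlation_ranking(sim$truth$sf_genes, prot, sim$events, calls,
                               top_k = 3)
  expect_equal(rk$ranking_all$sf[1], sim$truth$driver_sf)
  expect_gt(rk$ranking_all$n_strong[1], 5)
  # uncoupled SFs have few strong correlations
  expect_lt(max(rk$ranking_all$n_strong[-1]), rk$ranking_all$n_strong[1])
  # top_k covering all SFs -> recurrent = everything ranked
  rk2 <- sf_correlation_ranking(sim$truth$sf_genes, prot, sim$events, calls,
                                top_k = 99)
  expect_setequal(rk2$recurrent, rk2$ranking_all$sf)
  expect_warning(
    sf_correlation_ranking(c(sim$truth$sf_genes, "ABSENT"), prot,
                           sim$events, calls),
    "absent")
})
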