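#' Configuration of a synthetic three-arm proteotranscriptomic cohort
#'
#' Defines the study conditions the generator emulates: a normal /
#' inflammation (IOI + RLH) / tumor design with per-sample-controllable
#' protein-mRNA rank concordance, planted trend-pattern genes, planted
#' aberrant splice events driven by a regulator protein, survival endpoints
#' coupled to concordance and event inclusion, and one planted diagnostic
#' marker protein.
#'
#' Defaults mirror a scaled-down ocular adnexal B-cell lymphoma cohort: group
#' concordance targets equal the reported subgroup medians (normal 0.16,
#' IOI 0.23, RLH 0.254, tumor 0.364), proteome DE effects are on the log2
#' scale of TMT-compressed abundances (noise sd 0.45), transcript noise sd is
#' 1 on the log2 scale, and inclusion levels are simulated on the logit scale
#' with noise sd 0.3.
#'
#' @param n_per_group samples per arm (normal, inflammation, tumor).
#' @param n_genes number of protein-mRNA pairs.
#' @param target_rho named per-group Spearman targets in \[-1, 1\]; names from
#'   `normal`, `IOI`, `RLH`, `inflammation`, `control`, `tumor` (coarser names
#'   expand to their subgroups).
#' @param rho_sd sd of the per-sample jitter around the group target.
#' @param n_pattern_genes genes planted per each of the nine trend patterns.
#' @param pattern_effect log2-fold step size of planted trend steps.
#' @param n_events splice events per ASE type (A3, A5, MX, RI, SE).
#' @param n_aberrant events per type with a planted tumor inclusion shift.
#' @param psi_effect planted |delta IncLevel| of aberrant events, in (0, 1).
#' @param psi_logit_sd sd of inclusion-level noise on the logit scale.
#' @param n_sf number of splicing-regulator proteins; the first is the driver.
#' @param sf_coupling correlation strength driver -> coupled events, \[0, 1\].
#' @param n_coupled_events aberrant events coupled to the driver regulator.
#' @param n_hazard_events coupled events carrying a progression (PFS) hazard.
#' @param hazard_event_beta log-hazard per unit IncLevel of hazard events.
#' @param marker_effect log2 tumor shift of the planted diagnostic protein.
#' @param reference_effect log2 shift of the two noisy reference markers
#'   (benchmark analogues of membrane B-cell markers; extra noise halves
#'   their discrimination). Set 0 to plant no reference signal.
#' @param mki67_coupling correlation of the proliferation-proxy protein with
#'   per-sample concordance in the tumor arm.
#' @param hazard_rho log-hazard per standard deviation of planted concordance
#'   on the distant-recurrence (DRFS) endpoint.
#' @param censor_rate expected censoring fraction in \[0, 1).
#' @param missing_rate MCAR missingness fraction of the protein layer, \[0, 1).
#' @param protein_sd,mrna_sd log2-scale noise sd of the two layers.
#' @param seed integer seed; same config (incl. seed) gives identical output.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_per_group = 20,
                         n_genes = 3000,
                         target_rho = c(normal = 0.16, IOI = 0.23,
                                        RLH = 0.254, tumor = 0.364),
                         rho_sd = 0.06,
                         n_pattern_genes = 12,
                         pattern_effect = 1,
                         n_events = 150,
                         n_aberrant = 30,
                         psi_effect = 0.2,
                         psi_logit_sd = 0.3,
                         n_sf = 20,
                         sf_coupling = 0.8,
                         n_coupled_events = 30,
                         n_hazard_events = 5,
                         hazard_event_beta = 10,
                         marker_effect = 1.5,
                         reference_effect = 0.75,
                         mki67_coupling = 0.5,
                         hazard_rho = 2,
                         censor_rate = 0.2,
                         missing_rate = 0.1,
                         protein_sd = 0.45,
                         mrna_sd = 1,
                         seed = 1) {
  cfg <- as.list(environment())
  cfg$target_rho <- expand_rho_targets(target_rho)
  with(cfg, {
    stopifnot(n_per_group > 0, n_genes > 0, n_pattern_genes > 0,
              n_events > 0, n_sf > 0,
              psi_effect > 0, psi_effect < 1,
              censor_rate >= 0, censor_rate < 1,
              missing_rate >= 0, missing_rate < 1,
              sf_coupling >= 0, sf_coupling <= 1,
              rho_sd >= 0, protein_sd > 0, mrna_sd > 0)
  })
  if (any(abs(cfg$target_rho) > 1))
    stopf("target_rho must lie in [-1, 1]")
  if (any(abs(cfg$target_rho) == 1) && cfg$rho_sd > 0)
    stopf(paste("infeasible coupling: |target_rho| = 1 requires rho_sd = 0;",
                "with rho_sd = %g the attainable bound is |rho| < 1"),
          cfg$rho_sd)
  if (9 * cfg$n_pattern_genes + 4 + cfg$n_sf > cfg$n_genes)
    stopf("n_genes too small for the planted gene inventory")
  if (cfg$n_aberrant > cfg$n_events)
    stopf("n_aberrant must not exceed n_events")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

expand_rho_targets <- function(tr) {
  out <- c(normal = 0.16, IOI = 0.23, RLH = 0.254, tumor = 0.364)
  if (is.null(names(tr))) stopf("target_rho must be named")
  for (nm in names(tr)) {
    val <- unname(tr[[nm]])
    sub <- switch(nm,
                  control = c("normal", "IOI", "RLH"),
                  inflammation = c("IOI", "RLH"),
                  nm)
    if (!all(sub %in% names(out))) stopf("unknown target_rho group '%s'", nm)
    out[sub] <- val
  }
  out
}

# the nine trend patterns: (normal->inflammation, inflammation->tumor) steps
trend_pattern_grid <- function() {
  g <- expand.grid(step1 = c("up", "down", "flat"),
                   step2 = c("up", "down", "flat"),
                   stringsAsFactors = FALSE)
  g$pattern <- paste(g$step1, g$step2, sep = "-")
  g
}

step_sign <- function(s) c(up = 1, down = -1, flat = 0)[s]

#' Simulate a synthetic cohort with planted ground truth
#'
#' Protein values are rank-coupled to mRNA values per sample through a
#' Gaussian copula whose latent correlation is solved from the per-sample
#' Spearman target (r = 2 sin(pi * rho_s / 6)), so realized per-sample rho
#' matches the target in expectation. Trend-pattern genes shift group means
#' on the log2 scale in both layers; inclusion levels are simulated on the
#' logit scale and squashed to (0, 1), with aberrant events shifted in the
#' tumor arm by `psi_effect` on the IncLevel scale and coupled to the driver
#' regulator's protein abundance; survival is exponential with independent
#' exponential censoring calibrated to `censor_rate`, with DRFS hazard tied
#' to standardized concordance and PFS hazard to planted event inclusion.
#' Missingness is applied completely at random to the protein layer only.
#'
#' @param config a [synth_config].
#' @return list with elements `cohort` (a `paired_cohort`: log2-scale protein
#'   with missing values, log2(FPKM+1) mRNA, and metadata), `events` (a
#'   `splice_event_table`), and `truth` (planted ground truth).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  G <- config$n_genes

  ## samples and subgroups -------------------------------------------------
  n_ioi <- ceiling(n / 2)
  subgroup <- c(rep("normal", n), rep("IOI", n_ioi), rep("RLH", n - n_ioi),
                rep("tumor", n))
  group <- c(rep("normal", n), rep("inflammation", n), rep("tumor", n))
  S <- length(group)
  samples <- sprintf("S%03d", seq_len(S))
  is_tumor <- group == "tumor"

  ## gene inventory ---------------------------------------------------------
  genes <- sprintf("G%05d", seq_len(G))
  grid <- trend_pattern_grid()
  np <- config$n_pattern_genes
  idx_pattern <- seq_len(9 * np)
  pattern_of <- rep(seq_len(9), each = np)
  nxt <- 9 * np
  idx_marker <- nxt + 1
  idx_ref <- nxt + 2:3
  idx_sf <- nxt + 3 + seq_len(config$n_sf)
  genes[idx_sf] <- sprintf("SF%03d", seq_len(config$n_sf))

  ## planted group effects (log2 scale, both layers) ------------------------
  eff <- matrix(0, G, S)
  for (k in seq_len(9)) {
    d1 <- step_sign(grid$step1[k]) * config$pattern_effect
    d2 <- step_sign(grid$step2[k]) * config$pattern_effect
    rows <- idx_pattern[pattern_of == k]
    eff[rows, group == "inflammation"] <- d1
    eff[rows, group == "tumor"] <- d1 + d2
  }

  ## mRNA layer: log2(FPKM + 1) scale ---------------------------------------
  mu_g <- stats::rnorm(G, 4, 1.5)
  mrna <- mu_g + eff + matrix(stats::rnorm(G * S, 0, config$mrna_sd), G, S)
  mrna[mrna < 0] <- 0

  ## per-sample planted rho and copula coupling ------------------------------
  target <- unname(config$target_rho[subgroup])
  rho_j <- target + stats::rnorm(S, 0, config$rho_sd)
  rho_j <- pmin(pmax(rho_j, -0.995), 0.995)
  rho_j[abs(target) == 1] <- target[abs(target) == 1]
  r_j <- 2 * sin(pi * rho_j / 6)

  lat <- matrix(0, G, S)
  for (j in seq_len(S)) {
    zm <- stats::qnorm((rank(mrna[, j], ties.method = "average") - 0.5) / G)
    noise <- if (abs(r_j[j]) == 1) 0 else stats::rnorm(G)
    lat[, j] <- r_j[j] * zm + sqrt(1 - r_j[j]^2) * noise
  }

  protein <- 6 + config$protein_sd * lat + eff
  protein[idx_marker, is_tumor] <- protein[idx_marker, is_tumor] +
    config$marker_effect
  if (config$reference_effect != 0) {
    # reference markers: shifted but noisy (weaker discrimination)
    protein[idx_ref, ] <- protein[idx_ref, ] +
      matrix(stats::rnorm(2 * S, 0, 0.9), 2, S)
    protein[idx_ref, is_tumor] <- protein[idx_ref, is_tumor] +
      config$reference_effect
  }

  ## proliferation proxy coupled to concordance in the tumor arm only.
  ## Carried in the metadata (MKI67_protein), not as a matrix row, so the
  ## rank coupling of the abundance layers stays exact.
  cmk <- config$mki67_coupling
  z_rho_t <- scale_or_zero(rho_j[is_tumor])
  mki <- stats::rnorm(S)
  mki[is_tumor] <- cmk * z_rho_t + sqrt(1 - cmk^2) * stats::rnorm(sum(is_tumor))
  mki67_protein <- 6 + config$protein_sd * mki

  ## splice events ------------------------------------------------------------
  driver_protein <- protein[idx_sf[1], ]
  z_drv <- stats::setNames(scale_or_zero(driver_protein), samples)
  ev <- simulate_events(config, genes, group, z_drv)

  ## protein missingness (MCAR) ----------------------------------------------
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(G * S) < config$missing_rate, G, S)
    protein[mask] <- NA_real_
  }
  dimnames(protein) <- dimnames(mrna) <- list(genes, samples)

  ## survival ------------------------------------------------------------------
  surv <- simulate_survival(config, rho_j, is_tumor, ev)

  ## metadata -------------------------------------------------------------------
  subtype <- rep("none", S)
  subtype[is_tumor] <- sample(c("EMZL", "DLBCL", "MCL", "SLL"), sum(is_tumor),
                              replace = TRUE, prob = c(0.7, 0.2, 0.05, 0.05))
  meta <- data.frame(
    sample = samples, group = group, subgroup = subgroup, subtype = subtype,
    LDH = sample(c("normal", "high"), S, replace = TRUE, prob = c(0.7, 0.3)),
    IPI = sample(0:3, S, replace = TRUE),
    AnnArbor = sample(c("I", "II", "III", "IV"), S, replace = TRUE,
                      prob = c(0.5, 0.3, 0.1, 0.1)),
    MKI67_protein = mki67_protein,
    stringsAsFactors = FALSE)
  meta <- cbind(meta, surv)

  cohort <- paired_cohort_obj(protein, mrna, meta)

  truth <- list(
    pattern = data.frame(gene = genes[idx_pattern],
                         step1 = grid$step1[pattern_of],
                         step2 = grid$step2[pattern_of],
                         pattern = grid$pattern[pattern_of],
                         stringsAsFactors = FALSE),
    marker = genes[idx_marker],
    references = genes[idx_ref],
    sf_genes = genes[idx_sf],
    driver_sf = genes[idx_sf[1]],
    rho = stats::setNames(rho_j, samples),
    events = ev$truth)

  list(cohort = cohort, events = ev$table, truth = truth)
}

scale_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

simulate_events <- function(config, genes, group, z_drv) {
  S <- length(group)
  is_tumor <- group == "tumor"
  per_type <- lapply(ase_types, function(tp) {
    data.frame(event_id = sprintf("%s_%04d", tp, seq_len(config$n_events)),
               type = tp,
               gene = sample(genes, config$n_events, replace = TRUE),
               aberrant = seq_len(config$n_events) <= config$n_aberrant,
               stringsAsFactors = FALSE)
  })
  info <- do.call(rbind, per_type)
  E <- nrow(info)
  mu_e <- stats::rnorm(E, 0, 1.2)

  # planted tumor-arm shift of psi_effect on the IncLevel scale
  sgn <- ifelse(stats::runif(E) < 0.5, -1, 1)
  base_psi <- expit(mu_e)
  tgt_psi <- pmin(pmax(base_psi + sgn * config$psi_effect, 0.02), 0.98)
  shift <- ifelse(info$aberrant, logit(tgt_psi) - mu_e, 0)
  planted_delta <- ifelse(info$aberrant, tgt_psi - base_psi, 0)

  ab_idx <- which(info$aberrant)
  coupled <- rep(FALSE, E)
  coupled[ab_idx[seq_len(min(config$n_coupled_events, length(ab_idx)))]] <- TRUE
  hazard_beta <- rep(0, E)
  # progression-hazard events come from the regulator-coupled set when one
  # exists (mirrors a splicing program driving progression); otherwise from
  # independent aberrant events. Mid-range baseline inclusion is preferred:
  # an event pinned near PSI 0 or 1 has almost no inclusion variance and
  # cannot carry an identifiable per-sample hazard.
  pool <- if (any(coupled)) which(coupled) else ab_idx
  pool <- pool[order(abs(mu_e[pool]))]
  hz <- pool[seq_len(min(config$n_hazard_events, length(pool)))]
  hazard_beta[hz] <- config$hazard_event_beta

  c_sf <- config$sf_coupling
  eta <- matrix(mu_e, E, S) + outer(shift, as.numeric(is_tumor))
  noise <- matrix(stats::rnorm(E * S), E, S)
  if (any(coupled))
    noise[coupled, ] <- c_sf * matrix(z_drv, sum(coupled), S, byrow = TRUE) +
      sqrt(1 - c_sf^2) * noise[coupled, , drop = FALSE]
  eta <- eta + config$psi_logit_sd * noise
  psi <- expit(eta)
  dimnames(psi) <- list(info$event_id, names(z_drv))

  truth <- cbind(info,
                 planted_delta = planted_delta,
                 coupled = coupled,
                 hazard_beta = hazard_beta)
  table <- splice_event_table_obj(info[, c("event_id", "type", "gene")],
                                  psi, stats::setNames(group, colnames(psi)))
  list(table = table, truth = truth)
}

simulate_survival <- function(config, rho_j, is_tumor, ev) {
  S <- length(rho_j)
  nt <- sum(is_tumor)
  lambda0 <- log(2) / 5
  z_rho <- scale_or_zero(rho_j[is_tumor])

  psi_t <- ev$table$psi[, is_tumor, drop = FALSE]
  hz <- which(ev$truth$hazard_beta != 0)
  lh_pfs <- rep(0, nt)
  for (e in hz) {
    x <- psi_t[e, ]
    lh_pfs <- lh_pfs + ev$truth$hazard_beta[e] * (x - mean(x))
  }

  loghaz <- list(PFS = lh_pfs, OS = rep(0, nt), RFS = rep(0, nt),
                 LRFS = rep(0, nt), DRFS = config$hazard_rho * z_rho)
  out <- data.frame(row.names = seq_len(S))
  for (ep in endpoint_names) {
    lam <- lambda0 * exp(loghaz[[ep]])
    tt <- stats::rexp(nt, lam)
    if (config$censor_rate > 0) {
      mu <- stats::uniroot(function(m) mean(m / (lam + m)) - config$censor_rate,
                           c(1e-8, 1e6))$root
      cc <- stats::rexp(nt, mu)
      evt <- as.integer(tt <= cc)
      tt <- pmin(tt, cc)
    } else evt <- rep(1L, nt)
    tcol <- rep(NA_real_, S); ecol <- rep(NA_integer_, S)
    tcol[is_tumor] <- tt; ecol[is_tumor] <- evt
    out[[paste0(ep, "_time")]] <- tcol
    out[[paste0(ep, "_event")]] <- ecol
  }
  out
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `protein.tsv` (raw abundance, i.e. 2^log2 values, NA for missing),
#' `mrna.tsv` (FPKM scale), `meta.tsv`, one rMATS-dialect junction-count table
#' per ASE type (`SE.MATS.JC.txt`, ...; IncLevel1 = tumor samples, IncLevel2 =
#' controls, in metadata order) and `ground_truth.json`. Files round-trip
#' through the package readers up to float formatting, and identical inputs
#' produce byte-identical files.
#'
#' @param sim result of [simulate_cohort] (or a list with `cohort`, `events`,
#'   `truth`).
#' @param dir_path output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(sim, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  co <- sim$cohort
  files <- character(0)

  wmat <- function(m, fname, raw_fun) {
    df <- data.frame(gene = rownames(m),
                     signif(raw_fun(m), 12),
                     check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(dir_path, fname)
    write_tsv(df, p)
    p
  }
  files <- c(files,
             wmat(co$protein, "protein.tsv", function(m) 2^m),
             wmat(co$mrna, "mrna.tsv", function(m) 2^m - 1))

  p <- file.path(dir_path, "meta.tsv")
  meta <- co$meta
  num <- vapply(meta, is.numeric, TRUE)
  meta[num] <- lapply(meta[num], function(x) signif(x, 12))
  write_tsv(meta, p)
  files <- c(files, p)

  ev <- sim$events
  grp <- ev$groups[colnames(ev$psi)]
  i1 <- which(grp == "tumor")
  i2 <- which(grp != "tumor")
  fmt_list <- function(v) paste(ifelse(is.na(v), "NA", sprintf("%.8f", v)),
                                collapse = ",")
  for (tp in unique(ev$info$type)) {
    rows <- which(ev$info$type == tp)
    psi <- ev$psi[rows, , drop = FALSE]
    m1 <- rowMeans(psi[, i1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(psi[, i2, drop = FALSE], na.rm = TRUE)
    pv <- vapply(rows, function(e) {
      a <- ev$psi[e, i1]; b <- ev$psi[e, i2]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      mann_whitney_u(a, b)$p_value
    }, numeric(1))
    df <- data.frame(
      ID = ev$info$event_id[rows],
      GeneID = ev$info$gene[rows],
      geneSymbol = ev$info$gene[rows],
      IncLevel1 = apply(psi[, i1, drop = FALSE], 1, fmt_list),
      IncLevel2 = apply(psi[, i2, drop = FALSE], 1, fmt_list),
      IncLevelDifference = sprintf("%.8f", m1 - m2),
      PValue = sprintf("%.8g", pv),
      FDR = sprintf("%.8g", bh_adjust(pv)),
      stringsAsFactors = FALSE)
    p <- file.path(dir_path, paste0(tp, ".MATS.JC.txt"))
    write_tsv(df, p)
    files <- c(files, p)
  }

  p <- file.path(dir_path, "ground_truth.json")
  jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, p)
  invisible(files)
}
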