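#' @name pipeline
#' @title Full-analysis pipeline
#'
#' @description
#' Orchestrates preprocess -> embed -> estimate -> statistics from one
#' configuration list: epoch QC, Ragwitz embedding optimization with the
#' common-dimension rule, KSG and/or NSB estimation of H, AIS and TE_SPO
#' with per-direction delay optimization, and the inference stage
#' (surrogate + binomial, permutation ANOVA, linear mixed models). Every
#' stochastic stage derives its seed from the single config seed, so an
#' identical config yields an identical results bundle.
NULL

#' Default pipeline configuration
#'
#' @param ... overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    synth = NULL,            # list(base = <synth_params args>, condition_map = ...)
    input_dir = NULL,        # or a directory of stored recordings
    delta_threshold = 0.30,
    amplitude_z = 8,
    delta_qc_conditions = NULL,  # conditions to apply delta QC to (NULL = none)
    embed = list(d_candidates = 1:3,
                 tau_act_fractions = c(0.5, 1.0),
                 k = 4, n_epochs_embed = 3),
    estimate = list(backend = "ksg", k = 4, u_grid = 1:10,
                    n_inner_bins = 10, n_scan_epochs = 10),
    stats = list(n_surrogates = 100, n_perm = 1000, alpha = 0.05,
                 surrogate_epochs = 50),
    seed = 1L,
    out_dir = NULL)
  utils::modifyList(cfg, list(...))
}

#' @noRd
.pipe_load_data <- function(cfg) {
  if (!is.null(cfg$synth)) {
    base <- do.call(synth_params, c(cfg$synth$base, list(seed = cfg$seed)))
    generate_condition_set(base, cfg$synth$condition_map)
  } else {
    .assert(!is.null(cfg$input_dir), "config needs either synth or input_dir")
    stems <- sub("\\.json$", "",
                 list.files(cfg$input_dir, pattern = "\\.json$",
                            full.names = TRUE))
    .assert(length(stems) > 0, "no recordings found in input_dir")
    lapply(sort(stems), load_recording)
  }
}

#' @noRd
.pipe_preprocess <- function(recs, cfg) {
  qc_rows <- list()
  out <- vector("list", length(recs))
  for (ri in seq_along(recs)) {
    rec <- recs[[ri]]
    raw <- rec$channels
    rec <- znormalize_recording(rec)
    rejected <- rep(FALSE, n_epochs(rec))
    for (ch in sites(rec)) {
      qa <- reject_by_amplitude(rec$channels[[ch]], z_max = cfg$amplitude_z)
      qd <- NULL
      if (!is.null(cfg$delta_qc_conditions) &&
          rec$condition %in% cfg$delta_qc_conditions)
        qd <- reject_by_delta(rec$channels[[ch]], rec$fs,
                              threshold = cfg$delta_threshold)
      rej <- qa$rejected | (if (is.null(qd)) FALSE else qd$rejected)
      qc_rows[[length(qc_rows) + 1]] <- data.frame(
        session_id = rec$session_id, channel = ch,
        epoch_index = qa$epoch_index,
        rejected = rej,
        reason = ifelse(qa$rejected, "artifact",
                        ifelse(rej, "delta_power", "")),
        relative_delta = if (is.null(qd)) NA_real_ else qd$relative_delta)
      rejected <- rejected | rej
    }
    keep <- which(!rejected)
    .assert(length(keep) >= 2, sprintf("QC left < 2 epochs in %s",
                                       rec$session_id))
    rec$channels <- lapply(rec$channels, function(m) m[keep, , drop = FALSE])
    # raw (pre-normalization) epochs kept for differential entropy: H is
    # translation- but not scale-invariant, and z-scoring would remove the
    # amplitude component of "locally available information"
    rec$raw <- lapply(raw, function(m) m[keep, , drop = FALSE])
    out[[ri]] <- rec
  }
  list(recordings = out, qc = do.call(rbind, qc_rows))
}

#' @noRd
.pipe_embed <- function(recs, cfg) {
  em <- cfg$embed
  specs <- list()
  per_rec <- list()
  for (rec in recs) {
    for (ch in sites(rec)) {
      ep <- rec$channels[[ch]]
      sub <- ep[seq_len(min(em$n_epochs_embed, nrow(ep))), , drop = FALSE]
      opt <- ragwitz_optimize(sub, d_candidates = em$d_candidates,
                              tau_act_fractions = em$tau_act_fractions,
                              k = em$k)
      key <- paste(rec$session_id, ch, sep = "|")
      per_rec[[key]] <- opt
      specs[[length(specs) + 1]] <- opt
    }
  }
  list(common_d = common_dimension(specs), per_rec = per_rec)
}

#' @noRd
.pipe_estimate_ksg <- function(recs, emb, cfg) {
  es <- cfg$estimate
  rows <- list()
  delays <- list()
  for (rec in recs) {
    ch <- sites(rec)
    tau_of <- function(site) emb$per_rec[[paste(rec$session_id, site,
                                                sep = "|")]]$tau
    d <- emb$common_d
    for (site in ch) {
      ep <- rec$channels[[site]]
      ep_raw <- if (is.null(rec$raw)) ep else rec$raw[[site]]
      for (e in seq_len(nrow(ep))) {
        rows[[length(rows) + 1]] <- data.frame(
          measure = "H", value = kl_entropy(ep_raw[e, ], k = es$k),
          unit = "nats", direction_or_site = site,
          condition = rec$condition, session_id = rec$session_id,
          epoch_index = e, k = es$k, d = 1, tau = NA, u = NA)
        rows[[length(rows) + 1]] <- data.frame(
          measure = "AIS",
          value = ais(ep[e, ], d = d, tau = tau_of(site), k = es$k,
                      record = FALSE),
          unit = "nats", direction_or_site = site,
          condition = rec$condition, session_id = rec$session_id,
          epoch_index = e, k = es$k, d = d, tau = tau_of(site), u = NA)
      }
    }
    dirs <- list(c(1, 2), c(2, 1))
    for (dd in dirs) {
      src <- rec$channels[[dd[1]]]; tgt <- rec$channels[[dd[2]]]
      lab <- paste(ch[dd[1]], ch[dd[2]], sep = "->")
      nsc <- min(es$n_scan_epochs, nrow(src))
      scan <- scan_delay(src[seq_len(nsc), , drop = FALSE],
                         tgt[seq_len(nsc), , drop = FALSE],
                         dX = emb$common_d, dY = emb$common_d,
                         tau = c(tau_of(ch[dd[1]]), tau_of(ch[dd[2]])),
                         u_grid = es$u_grid, k = es$k)
      delays[[paste(rec$session_id, lab, sep = "|")]] <- scan
      for (e in seq_len(nrow(src))) {
        rows[[length(rows) + 1]] <- data.frame(
          measure = "TE_SPO",
          value = te_spo(src[e, ], tgt[e, ], dX = emb$common_d,
                         dY = emb$common_d,
                         tau = c(tau_of(ch[dd[1]]), tau_of(ch[dd[2]])),
                         u = scan$u_opt, k = es$k, record = FALSE),
          unit = "nats", direction_or_site = lab,
          condition = rec$condition, session_id = rec$session_id,
          epoch_index = e, k = es$k, d = emb$common_d,
          tau = tau_of(ch[dd[1]]), u = scan$u_opt)
      }
    }
  }
  list(estimates = do.call(rbind, rows), delays = delays)
}

#' @noRd
.pipe_estimate_nsb <- function(recs, emb, cfg) {
  es <- cfg$estimate
  rows <- list()
  for (rec in recs) {
    ch <- sites(rec)
    tau_of <- function(site) emb$per_rec[[paste(rec$session_id, site,
                                                sep = "|")]]$tau
    d <- emb$common_d
    for (site in ch) {
      ep <- rec$channels[[site]]
      sym <- discretize(ep, es$n_inner_bins)
      wc <- state_words(sym, d = 1, role = "present",
                        n_bins = es$n_inner_bins + 2)
      rows[[length(rows) + 1]] <- data.frame(
        measure = "H", value = nsb_entropy(wc), unit = "bits",
        direction_or_site = site, condition = rec$condition,
        session_id = rec$session_id, epoch_index = "pooled",
        k = NA, d = 1, tau = NA, u = NA)
      a <- ais_decomposed(ep, d = d, tau = tau_of(site),
                          n_inner_bins = es$n_inner_bins)
      rows[[length(rows) + 1]] <- data.frame(
        measure = "AIS", value = a$value, unit = "bits",
        direction_or_site = site, condition = rec$condition,
        session_id = rec$session_id, epoch_index = "pooled",
        k = NA, d = d, tau = tau_of(site), u = NA)
    }
    for (dd in list(c(1, 2), c(2, 1))) {
      lab <- paste(ch[dd[1]], ch[dd[2]], sep = "->")
      u_mid <- es$u_grid[ceiling(length(es$u_grid) / 2)]
      te <- te_decomposed(rec$channels[[dd[1]]], rec$channels[[dd[2]]],
                          dX = d, dY = d,
                          tau = c(tau_of(ch[dd[1]]), tau_of(ch[dd[2]])),
                          u = u_mid, n_inner_bins = es$n_inner_bins)
      rows[[length(rows) + 1]] <- data.frame(
        measure = "TE_SPO", value = te$value, unit = "bits",
        direction_or_site = lab, condition = rec$condition,
        session_id = rec$session_id, epoch_index = "pooled",
        k = NA, d = d, tau = tau_of(ch[dd[1]]), u = u_mid)
    }
  }
  do.call(rbind, rows)
}

#' @noRd
.pipe_stats <- function(recs, est_ksg, cfg) {
  st <- cfg$stats
  tab <- est_ksg$estimates
  out <- list()
  # surrogate tests + binomial aggregation, reference condition only
  conds <- unique(vapply(recs, function(r) r$condition, character(1)))
  ref <- conds[1]
  surro <- list()
  for (rec in recs[vapply(recs, function(r) r$condition == ref,
                          logical(1))]) {
    ch <- sites(rec)
    for (dd in list(c(1, 2), c(2, 1))) {
      lab <- paste(ch[dd[1]], ch[dd[2]], sep = "->")
      scan <- est_ksg$delays[[paste(rec$session_id, lab, sep = "|")]]
      ne_use <- min(st$surrogate_epochs, n_epochs(rec))
      src <- rec$channels[[dd[1]]][seq_len(ne_use), , drop = FALSE]
      tgt <- rec$channels[[dd[2]]][seq_len(ne_use), , drop = FALSE]
      d <- unique(tab$d[tab$measure == "TE_SPO"])[1]
      res <- surrogate_test(src, tgt, function(s, t)
        te_spo(s, t, dX = d, dY = d, tau = 1, u = scan$u_opt,
               k = cfg$estimate$k, record = FALSE),
        n_surrogates = st$n_surrogates,
        seed = .substream(cfg$seed, 3, sum(utf8ToInt(rec$session_id)),
                          dd[1]))
      surro[[length(surro) + 1]] <- data.frame(
        session_id = rec$session_id, direction = lab, observed = res$observed,
        p = res$p, significant = res$p < st$alpha)
    }
  }
  surro <- do.call(rbind, surro)
  out$surrogate <- surro
  out$binomial <- do.call(rbind, lapply(split(surro, surro$direction),
    function(s) data.frame(direction = s$direction[1],
                           n_significant = sum(s$significant),
                           n_recordings = nrow(s),
                           p = binomial_aggregate(sum(s$significant),
                                                  nrow(s), st$alpha))))
  # permutation ANOVAs on per-recording medians
  med <- aggregate_by_recording(tab)
  out$panova <- list()
  for (m in unique(med$measure)) {
    sub <- med[med$measure == m, ]
    an <- perm_anova_2way(sub$value, sub$condition, sub$direction_or_site,
                          n_perm = st$n_perm,
                          seed = .substream(cfg$seed, 5, sum(utf8ToInt(m))))
    out$panova[[m]] <- list(F_main_condition = an$F_main_A,
                            p_main_condition = an$p_main_A,
                            F_main_B = an$F_main_B, p_main_B = an$p_main_B,
                            F_interaction = an$F_interaction,
                            p_interaction = an$p_interaction,
                            factor_B = if (m == "TE_SPO") "direction"
                                       else "recording_site",
                            n_perm = an$n_perm)
  }
  # linear mixed model on per-epoch TE values
  te <- tab[tab$measure == "TE_SPO", ]
  lm_tab <- data.frame(value = te$value, direction = te$direction_or_site,
                       condition = te$condition, session_id = te$session_id)
  lc <- lmm_compare(lm_tab)
  out$lmm <- lc$table
  out$icc <- icc(lm_tab)
  out
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()] list.
#' @return A results bundle: recordings (post-QC), QC table, embedding
#'   summary, estimate tables per backend, and the stats report. When
#'   `config$out_dir` is set the bundle is also written to disk (TSV
#'   tables + JSON stats, plus the config for provenance).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  recs <- .pipe_load_data(cfg)
  pre <- .pipe_preprocess(recs, cfg)
  emb <- .pipe_embed(pre$recordings, cfg)
  backend <- cfg$estimate$backend
  est_ksg <- NULL; est_nsb <- NULL
  if (backend %in% c("ksg", "both"))
    est_ksg <- .pipe_estimate_ksg(pre$recordings, emb, cfg)
  if (backend %in% c("nsb", "both"))
    est_nsb <- .pipe_estimate_nsb(pre$recordings, emb, cfg)
  stats_rep <- if (!is.null(est_ksg)) .pipe_stats(pre$recordings, est_ksg,
                                                  cfg)
  agreement <- NULL
  if (!is.null(est_ksg) && !is.null(est_nsb)) {
    # qualitative agreement is judged on AIS and TE only: the voltage
    # binning of the Bayesian route adapts to the signal SD, so condition
    # effects carried purely by amplitude are invisible to it
    sign_of <- function(tab) {
      med <- aggregate_by_recording(tab)
      conds <- sort(unique(med$condition))
      ms <- intersect(unique(med$measure), c("AIS", "TE_SPO"))
      vapply(setNames(ms, ms), function(m) {
        s <- med[med$measure == m, ]
        sign(median(s$value[s$condition == conds[length(conds)]]) -
               median(s$value[s$condition == conds[1]]))
      }, numeric(1))
    }
    s1 <- sign_of(est_ksg$estimates); s2 <- sign_of(est_nsb)
    agreement <- all(s1[names(s2)] == s2)
  }
  bundle <- list(config = cfg, qc = pre$qc, embedding = emb,
                 estimates_ksg = if (!is.null(est_ksg)) est_ksg$estimates,
                 delays = if (!is.null(est_ksg)) est_ksg$delays,
                 estimates_nsb = est_nsb, stats = stats_rep,
                 backend_agreement = agreement)
  if (!is.null(cfg$out_dir)) .write_bundle(bundle, cfg$out_dir)
  bundle
}

#' @noRd
.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(bundle$qc, "qc.tsv")
  wt(bundle$estimates_ksg, "estimates_ksg.tsv")
  wt(bundle$estimates_nsb, "estimates_nsb.tsv")
  stats <- bundle$stats
  if (!is.null(stats)) {
    stats$lmm <- as.list(stats$lmm)
    jsonlite::write_json(
      list(surrogate = stats$surrogate, binomial = stats$binomial,
           panova = stats$panova, lmm = stats$lmm, icc = stats$icc,
           backend_agreement = bundle$backend_agreement,
           seed = bundle$config$seed),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = 10,
      dataframe = "rows")
  }
  cfg <- bundle$config
  cfg$synth$condition_map <- lapply(cfg$synth$condition_map, as.list)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
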