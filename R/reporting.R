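#' Run a named analysis preset and write a reproducible output bundle
#'
#' Executes one of the package's figure-style analyses under a configuration
#' list and writes a deterministic directory layout: `curves/*.csv`,
#' `encoders/*.json`, `manifest.json` and `log.txt`. Rerunning with an
#' identical configuration and seed gives byte-identical CSV output.
#'
#' @param config A list with elements `analysis` (one of
#'   `r paste0('"', names(pib_presets()), '"', collapse = ", ")`),
#'   `params` (preset-specific overrides), `out_dir`, `seed`, and `plots`
#'   (logical; write PNG figures). Unknown parameter keys are rejected.
#' @return Invisibly, the manifest list. On partial failure the manifest is
#'   still written with `status = "failed"` and the failing stage.
#' @export
run_analysis <- function(config) {
  stopifnot(is.list(config), !is.null(config$analysis), !is.null(config$out_dir))
  presets <- pib_presets()
  if (!config$analysis %in% names(presets)) {
    stop("unknown analysis: ", config$analysis, call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  params <- config$params %||% list()
  preset <- presets[[config$analysis]]
  bad <- setdiff(names(params), names(preset$defaults))
  if (length(bad)) stop("unknown parameter keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  params <- utils::modifyList(preset$defaults, params)
  out <- config$out_dir
  dir.create(file.path(out, "curves"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "encoders"), showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  manifest <- list(analysis = config$analysis, params = params, seed = seed,
                   package_version = as.character(utils::packageVersion("pibop")),
                   config_hash = rlang::hash(list(config$analysis, params, seed)),
                   status = "running")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...,
                               "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logline("start ", config$analysis, " seed=", seed)
  res <- tryCatch({
    preset$run(params, seed, out, isTRUE(config$plots))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    manifest$status <- "failed"
    manifest$error <- conditionMessage(res)
    logline("FAILED: ", conditionMessage(res))
  } else {
    manifest$status <- "ok"
    manifest$outputs <- res
    logline("done")
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analysis presets
#'
#' Named presets replicating the package's standard analyses; each maps to
#' one of the worked figures of the methods vignette.
#'
#' @return A named list of presets (internal structure).
#' @export
pib_presets <- function() {
  list(
    fig3 = list(
      defaults = list(zeta = 0.5, dt = 1),
      run = function(p, seed, out, plots) {
        j <- sddho_joint(sddho_params(p$zeta, p$dt))
        cv <- info_curve(j)
        write_curve_csv(cv, file.path(out, "curves", "ib_curve.csv"))
        if (plots) save_plot(autoplot(cv), file.path(out, "ib_curve.png"))
        list(curve = "curves/ib_curve.csv")
      }
    ),
    fig4 = list(
      defaults = list(zeta = c(0.25, 1, 4), dt = c(0.1, 1, 10), i_past = 5),
      run = function(p, seed, out, plots) {
        sw <- fixed_info_sweep(p$zeta, p$dt, p$i_past)
        utils::write.csv(as.data.frame(sw),
                         file.path(out, "curves", "sweep.csv"),
                         row.names = FALSE, quote = FALSE)
        if (plots) save_plot(plot_conditional_ellipses(sw),
                             file.path(out, "ellipses.png"))
        list(sweep = "curves/sweep.csv")
      }
    ),
    fig6 = list(
      defaults = list(zeta = 1, dt = 1, i_past = 1, n_zeta = 12, n_dt = 12),
      run = function(p, seed, out, plots) {
        tm <- q_transfer(sddho_params(p$zeta, p$dt), p$i_past,
                         n_zeta = p$n_zeta, n_dt = p$n_dt)
        utils::write.csv(as.data.frame(tm$surface),
                         file.path(out, "curves", "transfer_surface.csv"),
                         row.names = FALSE, quote = FALSE)
        jsonlite::write_json(list(q = tm$q), file.path(out, "q.json"),
                             auto_unbox = TRUE, digits = NA)
        if (plots) save_plot(autoplot(tm), file.path(out, "transfer_map.png"))
        list(surface = "curves/transfer_surface.csv", q = tm$q)
      }
    ),
    fig7 = list(
      defaults = list(alpha = 0.5, dt = 1, t0_list = c(0, 0.25, 0.5, 1, 2),
                      n_traj = 6, traj_len = 1500),
      run = function(p, seed, out, plots) {
        gp <- gle_params(alpha = p$alpha, dt_pred = p$dt, t0 = max(p$t0_list))
        sat <- saturation_curve(gp, p$t0_list, n_traj = p$n_traj,
                                traj_len = p$traj_len, seed = seed)
        utils::write.csv(as.data.frame(sat),
                         file.path(out, "curves", "saturation.csv"),
                         row.names = FALSE, quote = FALSE)
        list(saturation = "curves/saturation.csv")
      }
    ),
    fig8 = list(
      defaults = list(N = 100, n_mu = 0.2, n_s = 0.001, dt = 1, m = 2,
                      beta = 4, n_restarts = 10),
      run = function(p, seed, out, plots) {
        j <- wf_joint(wf_params(p$N, p$n_mu, p$n_s, p$dt))
        enc <- ba_best(j, p$m, p$beta, n_restarts = p$n_restarts, seed = seed)
        write_encoder_json(enc, file.path(out, "encoders", "m2.json"))
        if (plots) save_plot(autoplot(enc, j), file.path(out, "decoders.png"))
        list(encoder = "encoders/m2.json",
             i_past_bits = enc$i_past_bits, i_future_bits = enc$i_future_bits)
      }
    ),
    fig9 = list(
      defaults = list(N = 100, n_mu_low = 0.2, n_mu_high = 20, n_s = 0.001,
                      dt = 1, n_restarts = 10),
      run = function(p, seed, out, plots) {
        res <- wf_transfer_experiment(
          n_mu_low = p$n_mu_low, n_mu_high = p$n_mu_high, N = p$N,
          n_s = p$n_s, dt_pred = p$dt, n_restarts = p$n_restarts, seed = seed)
        utils::write.csv(as.data.frame(res$table),
                         file.path(out, "curves", "transfer_table.csv"),
                         row.names = FALSE, quote = FALSE)
        write_encoder_json(res$encoder_low,
                           file.path(out, "encoders", "low.json"))
        write_encoder_json(res$encoder_high,
                           file.path(out, "encoders", "high.json"))
        list(table = "curves/transfer_table.csv")
      }
    ),
    fig10 = list(
      defaults = list(N = 100, n_s = 0.001, dt = 1,
                      n_mu_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20)),
      run = function(p, seed, out, plots) {
        mi <- vapply(p$n_mu_grid, function(nm) {
          wf_joint(wf_params(p$N, nm, p$n_s, p$dt))$mi_bits
        }, 0)
        df <- tibble::tibble(n_mu = p$n_mu_grid, mi_bits = mi)
        utils::write.csv(as.data.frame(df),
                         file.path(out, "curves", "mi_vs_nmu.csv"),
                         row.names = FALSE, quote = FALSE)
        list(mi = "curves/mi_vs_nmu.csv")
      }
    ),
    fig11 = list(
      defaults = list(N = 100, n_mu = 0.2, n_s = 0.001, dt = 1, m = 200,
                      betas = c(1.01, 20), n_restarts = 10),
      run = function(p, seed, out, plots) {
        j <- wf_joint(wf_params(p$N, p$n_mu, p$n_s, p$dt))
        rows <- lapply(p$betas, function(b) {
          enc <- ba_annealed(j, p$m, b, seed = seed,
                             n_restarts = p$n_restarts)
          write_encoder_json(enc, file.path(
            out, "encoders", sprintf("m%d_beta%g.json", p$m, b)))
          tibble::tibble(beta = b, i_past_bits = enc$i_past_bits,
                         i_future_bits = enc$i_future_bits)
        })
        df <- dplyr::bind_rows(rows)
        utils::write.csv(as.data.frame(df),
                         file.path(out, "curves", "m200.csv"),
                         row.names = FALSE, quote = FALSE)
        list(table = "curves/m200.csv")
      }
    ),
    s1fig = list(
      defaults = list(zeta = c(0.5, 1, 2), dt = 1,
                      obs_noise = exp(seq(log(1e-3), log(1e3), length.out = 15))),
      run = function(p, seed, out, plots) {
        rows <- lapply(p$zeta, function(z) {
          kc <- kalman_curve(sddho_params(z, p$dt), p$obs_noise)
          dplyr::mutate(kc, zeta = z, .before = 1)
        })
        df <- dplyr::bind_rows(rows)
        utils::write.csv(as.data.frame(df),
                         file.path(out, "curves", "kalman.csv"),
                         row.names = FALSE, quote = FALSE)
        list(kalman = "curves/kalman.csv")
      }
    )
  )
}

save_plot <- function(p, path) {
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
}

#' Wright-Fisher cross-mutability transfer experiment
#'
#' Trains m = 2 bottleneck encoders on a low- and a high-mutation model at
#' the tradeoff `beta` (default 4, which saturates the binary channel of the
#' slowly mixing low-mutation model), then evaluates each encoder both on
#' its own model and frozen on the other model.
#'
#' @param n_mu_low,n_mu_high Scaled mutation rates of the two models.
#' @param N,n_s,dt_pred Shared model parameters.
#' @param beta Tradeoff used for both solves.
#' @param n_restarts Restarts per solve.
#' @param seed Master seed.
#' @return A list with `table` (tibble: direction, i_past_bits,
#'   i_future_bits), `encoder_low`, `encoder_high`, and the two joints.
#' @export
wf_transfer_experiment <- function(n_mu_low = 0.2, n_mu_high = 20, N = 100,
                                   n_s = 0.001, dt_pred = 1, beta = 4,
                                   n_restarts = 10, seed = 1L) {
  j_lo <- wf_joint(wf_params(N, n_mu_low, n_s, dt_pred))
  j_hi <- wf_joint(wf_params(N, n_mu_high, n_s, dt_pred))
  enc_lo <- ba_best(j_lo, 2, beta, n_restarts = n_restarts, seed = seed)
  enc_hi <- ba_best(j_hi, 2, beta, n_restarts = n_restarts, seed = seed)
  tab <- dplyr::bind_rows(
    dplyr::mutate(discrete_info(enc_lo, j_lo), direction = "optimal_low"),
    dplyr::mutate(transfer_discrete(enc_hi, j_lo), direction = "high_to_low"),
    dplyr::mutate(discrete_info(enc_hi, j_hi), direction = "optimal_high"),
    dplyr::mutate(transfer_discrete(enc_lo, j_hi), direction = "low_to_high")
  )
  list(table = dplyr::relocate(tab, "direction"),
       encoder_low = enc_lo, encoder_high = enc_hi,
       joint_low = j_lo, joint_high = j_hi)
}

#' Blahut-Arimoto solve at a near-saturating tradeoff
#'
#' Anneals the tradeoff upward (doubling from `beta0`, warm-started) until
#' the encoded past information grows by less than `gain_tol` bits, i.e.
#' until the m-value channel is effectively saturated.
#'
#' @inheritParams ba_best
#' @param beta0 Starting tradeoff.
#' @param gain_tol Stop when i_past grows less than this many bits.
#' @param max_doublings Cap on the anneal length.
#' @return A `pib_discrete_encoder` (its `beta` is the stopping tradeoff).
#' @export
ba_saturated <- function(joint, m, beta0 = 4, gain_tol = 0.02,
                         max_doublings = 5L, n_restarts = 10L, seed = 1L,
                         tol = 1e-10, max_iter = 50000L) {
  enc <- ba_best(joint, m, beta0, n_restarts, seed, tol, max_iter)
  b <- beta0
  for (k in seq_len(max_doublings)) {
    b2 <- b * 2
    enc2 <- ba_best(joint, m, b2, n_restarts, seed, tol, max_iter,
                    warm = enc$q)
    if (enc2$i_past_bits - enc$i_past_bits < gain_tol) {
      return(if (enc2$i_future_bits >= enc$i_future_bits) enc2 else enc)
    }
    enc <- enc2
    b <- b2
  }
  enc
}

#' Annealed Blahut-Arimoto solve
#'
#' Sweeps beta upward on a log grid ending at `beta`, warm-starting each
#' solve from the previous solution (tracking the physical branch through
#' its bifurcations), with independent restarts at the final beta.
#'
#' @inheritParams ba_best
#' @param beta Final tradeoff.
#' @param n_anneal Number of anneal stages.
#' @return A `pib_discrete_encoder` at `beta`.
#' @export
ba_annealed <- function(joint, m, beta, n_anneal = 8L, n_restarts = 10L,
                        seed = 1L, tol = 1e-10, max_iter = 50000L) {
  if (beta <= 1.05 || n_anneal <= 1L) {
    return(ba_best(joint, m, beta, n_restarts, seed, tol, max_iter))
  }
  grid <- exp(seq(log(1.01), log(beta), length.out = n_anneal))
  warm <- NULL
  for (b in grid) {
    enc <- ba_best(joint, m, b, n_restarts = 2L, seed = seed, tol = tol,
                   max_iter = max_iter, warm = warm)
    warm <- enc$q
  }
  ba_best(joint, m, beta, n_restarts, seed, tol, max_iter, warm = warm)
}
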