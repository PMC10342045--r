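#' Pipeline configuration
#'
#' Collects every tunable of the featurize - TICA - cluster - MSM -
#' PCCA+ - flux pipeline with validation. The defaults are the
#' bromodomain-study preset: 0.1 ns frames, TICA and MSM lag of 10
#' frames (1 ns), k = 10 microstates from 10 k-means restarts, 5
#' macrostates, Chapman-Kolmogorov test up to k = 5.
#'
#' @param tica_lag,msm_lag Lags in frames (>= 1).
#' @param tica_dim Retained TICA dimension (integer, default 10:
#'   comfortably above the number of sought macrostates) or a kinetic
#'   variance fraction in (0, 1) passed to [estimate_tica()].
#' @param k Number of microstates, ignored when `k_grid` is given.
#' @param k_grid Optional candidate k values for VAMP-2 selection.
#' @param n_restarts k-means restarts.
#' @param its_lags Lag grid for the implied-timescale table.
#' @param ck_kmax Chapman-Kolmogorov multiples tested.
#' @param pcca_m Number of macrostates (>= 2).
#' @param endpoint_window Frames used for source/sink auto-detection.
#' @param A,B Optional explicit macrostate source/sink sets (0-based).
#' @param dt Frame spacing in ns.
#' @param sincos Apply [sincos_embed()] to periodic features.
#' @param reversible Detailed-balance MSM estimation.
#' @param seed Master seed for all stochastic stages.
#' @param use_cache Reuse a serialized TICA model found in the output
#'   directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tica_lag = 10L, tica_dim = 10L, k = 10L,
                            k_grid = NULL, n_restarts = 10L,
                            its_lags = c(1L, 2L, 5L, 10L, 20L),
                            msm_lag = 10L, ck_kmax = 5L, pcca_m = 5L,
                            endpoint_window = 100L, A = NULL, B = NULL,
                            dt = 0.1, sincos = TRUE, reversible = TRUE,
                            seed = 42L, use_cache = FALSE) {
  stopifnot_scalar_count(tica_lag, "tica_lag")
  stopifnot_scalar_count(msm_lag, "msm_lag")
  stopifnot_scalar_count(k, "k")
  stopifnot_scalar_count(n_restarts, "n_restarts")
  stopifnot_scalar_count(ck_kmax, "ck_kmax")
  stopifnot_scalar_count(pcca_m, "pcca_m", min = 2L)
  if (dt <= 0) stop("'dt' must be positive")
  structure(list(tica_lag = tica_lag, tica_dim = tica_dim, k = k,
                 k_grid = k_grid, n_restarts = n_restarts,
                 its_lags = its_lags, msm_lag = msm_lag,
                 ck_kmax = ck_kmax, pcca_m = pcca_m,
                 endpoint_window = endpoint_window, A = A, B = B,
                 dt = dt, sincos = sincos, reversible = reversible,
                 seed = seed, use_cache = use_cache),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full MSM / flux pipeline
#'
#' Executes featurization embedding, TICA, microstate clustering,
#' implied timescales, MSM estimation, the Chapman-Kolmogorov test,
#' PCCA+ coarse-graining, endpoint detection and transition-path flux
#' decomposition, serializing every stage's artifact into
#' `output_dir` and returning the assembled results. Transition-path
#' theory is computed on the microstates and then coarse-grained onto
#' the macrostates.
#'
#' @param trajs Input trajectories: a `synthetic_dataset`, a list of
#'   [feature_trajectory()]/matrices, or a character vector of feature
#'   matrix files.
#' @param config A [pipeline_config()].
#' @param output_dir Run directory (created if needed); `NULL` skips
#'   serialization.
#' @return List of class `pipeline_result` with elements `tica`,
#'   `cluster`, `dtrajs`, `its`, `msm`, `ck`, `partition`,
#'   `endpoints`, `state_names`, `flux_micro`, `flux_macro`, `decomp`,
#'   `table`, `log`.
#' @export
run_pipeline <- function(trajs, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(trajs, "synthetic_dataset")) trajs <- trajs$trajectories
  if (is.character(trajs)) {
    trajs <- lapply(trajs, read_feature_matrix, dt = config$dt)
  }
  trajs <- as_traj_list(trajs, dt = config$dt)
  log <- character(0)
  t_start <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t_start,
                   sprintf(fmt, ...))
    log <<- c(log, msg)
    message(msg)
  }
  art <- function(name) if (is.null(output_dir)) NULL else file.path(output_dir, name)
  if (!is.null(output_dir)) dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- featurization embedding ------------------------------------
  emb <- stage("featurize", {
    if (config$sincos && any(unlist(lapply(trajs, function(t) t$periodic)))) {
      say("featurize: sin/cos embedding %d periodic features",
          sum(trajs[[1]]$periodic))
      lapply(trajs, sincos_embed)
    } else {
      say("featurize: features used as supplied")
      trajs
    }
  })

  # --- TICA ---------------------------------------------------------
  tica <- stage("tica", {
    cache <- art("tica_model.yaml")
    if (config$use_cache && !is.null(cache) && file.exists(cache)) {
      say("tica: skipped (cached model loaded)")
      read_tica_model(cache)
    } else {
      m <- estimate_tica(emb, lag = config$tica_lag, dim = config$tica_dim)
      say("tica: lag %d, retained %d components (leading eigenvalue %.4f)",
          m$lag, m$dim, m$eigenvalues[1])
      if (!is.null(cache)) write_tica_model(m, cache)
      m
    }
  })
  ics <- lapply(emb, function(t) tica_transform(tica, t))

  # --- clustering ---------------------------------------------------
  seeds <- with_local_seed(config$seed,
                           sample.int(.Machine$integer.max, 4L))
  sel <- NULL
  k_use <- config$k
  if (!is.null(config$k_grid)) {
    sel <- stage("select_k", {
      s <- select_k(ics, config$k_grid, lag = config$msm_lag,
                    n_restarts = config$n_restarts, seed = seeds[1])
      say("select_k: best k = %d (VAMP-2 grid over {%s})", s$best_k,
          paste(config$k_grid, collapse = ", "))
      if (!is.null(output_dir)) {
        utils::write.csv(s$table, art("vamp_scores.csv"), row.names = FALSE)
      }
      s
    })
    k_use <- sel$best_k
  }
  cluster <- stage("cluster", {
    cm <- kmeans_fit(ics, k_use, n_restarts = config$n_restarts,
                     seed = seeds[2])
    say("cluster: k = %d, inertia %.4g", cm$k, cm$inertia)
    cm
  })
  dtrajs <- assign_microstates(cluster, ics)
  if (!is.null(output_dir)) {
    for (i in seq_along(dtrajs)) {
      write_dtraj(dtrajs[[i]], art(sprintf("dtraj_%02d.txt", i)))
    }
  }

  # --- implied timescales ------------------------------------------
  its <- stage("its", {
    lags_ok <- config$its_lags[config$its_lags <
                                 max(vapply(dtrajs, length, integer(1)))]
    tab <- implied_timescales(dtrajs, lags_ok, reversible = config$reversible,
                              dt = config$dt)
    say("its: %d lags evaluated", nrow(tab))
    if (!is.null(output_dir)) utils::write.csv(tab, art("its.csv"), row.names = FALSE)
    tab
  })

  # --- MSM ----------------------------------------------------------
  msm <- stage("msm", {
    m <- estimate_msm(dtrajs, lag = config$msm_lag,
                      reversible = config$reversible, dt = config$dt)
    say("msm: %d active states at lag %d (%g ns)", length(m$active_set),
        m$lag, m$lag * m$dt)
    if (!is.null(output_dir)) {
      write_state_matrix(m$count_matrix, art("count_matrix.csv"))
      write_state_matrix(m$transition_matrix, art("transition_matrix.csv"),
                         labels = m$active_set)
    }
    m
  })

  # --- PCCA+ --------------------------------------------------------
  partition <- stage("pcca", {
    p <- pcca_plus(msm, m = config$pcca_m)
    say("pcca: %d macrostates, weights (%s)", p$m,
        paste(signif(p$weights, 3), collapse = ", "))
    if (!is.null(output_dir)) write_partition(p, art("partition.csv"))
    p
  })

  # --- Chapman-Kolmogorov on the macrostates ------------------------
  ck <- stage("cktest", {
    r <- ck_test(msm, dtrajs, k_max = config$ck_kmax, sets = partition)
    say("cktest: k = 1..%d, max relative deviation %.3g (%s)",
        config$ck_kmax, max(r$max_rel_dev, na.rm = TRUE),
        if (r$pass) "pass" else "FAIL")
    if (!is.null(output_dir)) {
      jsonlite::write_json(list(k = r$k, max_rel_dev = r$max_rel_dev,
                                pass = r$pass),
                           art("ck_test.json"), auto_unbox = TRUE, digits = NA)
    }
    r
  })

  # --- endpoints and flux ------------------------------------------
  macro_dtrajs <- coarse_grain_dtrajs(partition, dtrajs)
  endpoints <- stage("endpoints", {
    e <- assign_endpoint_states(macro_dtrajs, window = config$endpoint_window,
                                A = config$A, B = config$B)
    say("endpoints: A = {%s}, B = {%s}", paste(e$A, collapse = ","),
        paste(e$B, collapse = ","))
    e
  })
  state_names <- macrostate_names(partition, endpoints$A, endpoints$B)

  flux <- stage("tpt", {
    A_micro <- partition$microstates[partition$crisp %in% endpoints$A]
    B_micro <- partition$microstates[partition$crisp %in% endpoints$B]
    # committors/flux over the active set in active-set coordinates
    to_active <- function(s) match(s, partition$microstates) - 1L
    fn <- reactive_flux(msm$transition_matrix, msm$stationary,
                        A = to_active(A_micro), B = to_active(B_micro),
                        dt = config$dt, lag = config$msm_lag)
    fm <- coarse_grain_flux(fn, list_groups_active(partition),
                            rho = msm$stationary)
    say("tpt: total A->B flux %.4g per lag step", fm$total_flux)
    if (!is.null(output_dir)) {
      write_flux_network(fm, art("flux_edges.csv"))
    }
    list(micro = fn, macro = fm)
  })

  decomp <- stage("pathways", {
    d <- decompose_pathways(flux$macro)
    say("pathways: %d paths, %.2f%% of flux decomposed", length(d$paths),
        100 * d$decomposed_flux / max(d$total_flux, 1e-300))
    d
  })
  tab <- flux_table(decomp, state_names = state_names)
  if (!is.null(output_dir)) {
    write_flux_table(tab, art("flux_table.tsv"))
    jsonlite::write_json(list(
      seed = config$seed, A = endpoints$A, B = endpoints$B,
      state_names = state_names,
      macro_committor_forward = flux$macro$qplus,
      total_flux = flux$macro$total_flux,
      ck_pass = ck$pass, log = log),
      art("report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log, art("run.log"))
  }

  structure(list(config = config, tica = tica, select_k = sel,
                 cluster = cluster, dtrajs = dtrajs, its = its, msm = msm,
                 ck = ck, partition = partition, endpoints = endpoints,
                 state_names = state_names, flux_micro = flux$micro,
                 flux_macro = flux$macro, decomp = decomp, table = tab,
                 log = log),
            class = "pipeline_result")
}

# macrostate -> microstate groups in active-set (0-based) coordinates
list_groups_active <- function(partition) {
  lapply(seq_len(partition$m) - 1L, function(k) {
    which(partition$crisp == k) - 1L
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(render_flux_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable flux report
#'
#' @param result A `pipeline_result`, or a run directory containing
#'   `flux_table.tsv` and `report.json`.
#' @return Character vector of report lines.
#' @export
render_flux_report <- function(result) {
  if (is.character(result)) {
    tab_path <- file.path(result, "flux_table.tsv")
    rep_path <- file.path(result, "report.json")
    if (!file.exists(tab_path) || !file.exists(rep_path)) {
      stop("run directory is missing the flux stage artifacts")
    }
    tab <- read_flux_table(tab_path)
    rep <- jsonlite::read_json(rep_path, simplifyVector = TRUE)
    nm <- rep$state_names
    qp <- rep$macro_committor_forward
    A <- rep$A; B <- rep$B
    total <- rep$total_flux
  } else {
    stopifnot(inherits(result, "pipeline_result"))
    tab <- result$table
    nm <- result$state_names
    qp <- result$flux_macro$qplus
    A <- result$endpoints$A; B <- result$endpoints$B
    total <- result$flux_macro$total_flux
  }
  lines <- c(
    sprintf("Source A: %s   Sink B: %s",
            paste(nm[A + 1L], collapse = ","),
            paste(nm[B + 1L], collapse = ",")),
    sprintf("Forward committor by macrostate: %s",
            paste(sprintf("%s=%.3f", nm, qp), collapse = "  ")),
    if (total > 0) "Pathway decomposition:" else "No reactive flux from A to B.",
    if (total > 0) utils::capture.output(print(tab, row.names = FALSE)))
  unlist(lines)
}
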