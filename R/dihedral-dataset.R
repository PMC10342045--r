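#' Emulate a backbone-dihedral trajectory dataset with planted states
#'
#' Generates a set of dihedral-like feature trajectories driven by a
#' hidden metastable Markov chain: each hidden state owns a distinct
#' mean angle vector, and every frame emits wrapped-Gaussian angles
#' around the mean of the current hidden state. The defaults reproduce
#' the data shape of a bromodomain simulation campaign — 10
#' trajectories of 5000 frames, 139 backbone-dihedral features at
#' 0.1 ns frame spacing — with 5 planted metastable states, so the full
#' TICA / clustering / MSM / PCCA+ / flux pipeline can be validated
#' against known ground truth.
#'
#' @param n_traj Number of trajectories.
#' @param n_frames Frames per trajectory.
#' @param n_features Angular features per frame (degrees, wrapped to
#'   (-180, 180]).
#' @param n_metastable Number of hidden metastable states.
#' @param noise_sd Emission noise around each state's mean angles,
#'   degrees.
#' @param p_hop Approximate per-frame probability of leaving the
#'   current hidden state (sets the mean dwell time, ~1/p_hop frames).
#' @param dt Frame spacing in ns.
#' @param start_state Hidden state (0-based) every trajectory starts
#'   in, or `NULL` to draw from the stationary distribution.
#' @param end_state If given, trajectories are redrawn (up to
#'   `max_retries` times) until the modal hidden state of the final
#'   `endpoint_window` frames equals this state, so endpoint
#'   auto-detection has a planted answer.
#' @param endpoint_window Window used for the `end_state` condition.
#' @param max_retries Redraw budget per trajectory for `end_state`.
#' @param seed Integer seed; the whole dataset is reproducible.
#'
#' @return An object of class `synthetic_dataset`: list with
#'   `trajectories` (list of [feature_trajectory()]),
#'   `ground_truth_labels` (list of 0-based integer vectors aligned
#'   frame-for-frame), `chain` (the hidden [ground_truth_chain()]),
#'   `state_means` (n_metastable x n_features), and `metadata`.
#' @export
#' @examples
#' ds <- emulate_dihedral_dataset(n_traj = 2, n_frames = 200,
#'                                n_features = 10, seed = 7)
#' dim(ds$trajectories[[1]]$values)
emulate_dihedral_dataset <- function(n_traj = 10L, n_frames = 5000L,
                                     n_features = 139L, n_metastable = 5L,
                                     noise_sd = 25, p_hop = 0.005,
                                     dt = 0.1, start_state = 0L,
                                     end_state = NULL,
                                     endpoint_window = 100L,
                                     max_retries = 100L, seed = NULL) {
  n_traj <- stopifnot_scalar_count(n_traj, "n_traj")
  n_frames <- stopifnot_scalar_count(n_frames, "n_frames")
  n_features <- stopifnot_scalar_count(n_features, "n_features")
  n_metastable <- stopifnot_scalar_count(n_metastable, "n_metastable")
  m <- n_metastable
  warnings <- character(0)

  with_local_seed(seed, {
    chain <- if (m == 1L) {
      ground_truth_chain(matrix(1, 1, 1))
    } else {
      # symmetric-weight chain over the hidden states; weight scale
      # chosen so the total leave probability per frame is ~ p_hop
      make_metastable_chain(m, states_per_block = 1L, p_intra = 0.4,
                            p_inter = p_hop / (m - 1L),
                            seed = sample.int(.Machine$integer.max, 1L))
    }
    means <- matrix(stats::runif(m * n_features, -180, 180), m, n_features)
    if (m > 1L) {
      dmin <- min(stats::dist(means))
      if (dmin < 2 * noise_sd * sqrt(n_features) / 4) {
        warnings <- c(warnings, sprintf(
          "state means separated by %.1f deg (Euclidean) vs noise scale %.1f; states may be indistinguishable",
          dmin, noise_sd * sqrt(n_features)))
      }
    }

    draw_labels <- function() {
      s <- if (is.null(start_state)) "stationary" else start_state
      sample_markov_chain(chain, n_frames, start = s,
                          seed = sample.int(.Machine$integer.max, 1L))
    }
    trajectories <- vector("list", n_traj)
    labels <- vector("list", n_traj)
    w <- min(endpoint_window, n_frames)
    for (i in seq_len(n_traj)) {
      lab <- draw_labels()
      if (!is.null(end_state)) {
        tries <- 0L
        modal_end <- function(l) {
          tl <- tabulate(l[(n_frames - w + 1L):n_frames] + 1L, nbins = m)
          which.max(tl) - 1L
        }
        while (modal_end(lab) != end_state && tries < max_retries) {
          lab <- draw_labels()
          tries <- tries + 1L
        }
        if (modal_end(lab) != end_state) {
          warnings <- c(warnings, sprintf(
            "trajectory %d: end_state %d not reached within %d retries", i,
            end_state, max_retries))
        }
      }
      angles <- means[lab + 1L, , drop = FALSE] +
        matrix(stats::rnorm(n_frames * n_features, sd = noise_sd),
               n_frames, n_features)
      trajectories[[i]] <- feature_trajectory(
        wrap_angle(angles), dt = dt,
        feature_names = paste0("dih", seq_len(n_features)),
        periodic = TRUE)
      labels[[i]] <- lab
    }

    structure(list(
      trajectories = trajectories,
      ground_truth_labels = labels,
      chain = chain,
      state_means = means,
      metadata = list(seed = seed, n_traj = n_traj, n_frames = n_frames,
                      n_features = n_features, n_metastable = m,
                      noise_sd = noise_sd, p_hop = p_hop, dt = dt,
                      start_state = start_state, end_state = end_state,
                      warnings = warnings)
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<synthetic_dataset> %d trajectories x %d frames x %d features, %d hidden states\n",
              md$n_traj, md$n_frames, md$n_features, md$n_metastable))
  if (length(md$warnings)) cat("warnings:", paste(md$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Feature matrices go to `traj_XX.txt` (whitespace text with a header
#' line), ground-truth labels to `labels_XX.txt` (one integer per
#' line), and generator metadata plus the hidden transition matrix to
#' `metadata.yaml`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$trajectories)) {
    write_feature_matrix(ds$trajectories[[i]],
                         file.path(dir, sprintf("traj_%02d.txt", i)))
    write_dtraj(ds$ground_truth_labels[[i]],
                file.path(dir, sprintf("labels_%02d.txt", i)))
  }
  meta <- ds$metadata
  Th <- ds$chain$transition_matrix
  meta$hidden_transition_matrix <- lapply(seq_len(nrow(Th)),
                                          function(i) as.numeric(Th[i, ]))
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}
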