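# Amplitude-by-frequency sweep experiments: entrainment grids,
# minimal-amplitude curves, and tongue-tip (resonance) extraction.

#' The five study parameter pairs
#'
#' Named presets of `(g_syn, I_app)`: the pallido-subthalamic conductance and
#' the GPe applied current. `(0.5, 5)` and `(0.7, 5)` sit inside the domain
#' of realistic Parkinsonian intermittent synchrony, `(0.9, 5)` is more
#' synchronous than that domain, `(0.5, 7)` and `(0.5, 9)` less.
#'
#' @return A tibble with columns `preset`, `g_syn`, `i_app`.
#' @export
sweep_presets <- function() {
  tibble::tibble(
    preset = c("g0.5_i5", "g0.5_i7", "g0.5_i9", "g0.7_i5", "g0.9_i5"),
    g_syn = c(0.5, 0.5, 0.5, 0.7, 0.9),
    i_app = c(5, 7, 9, 5, 5)
  )
}

#' Run an amplitude-by-frequency sweep
#'
#' One network simulation (or several replicates) per grid cell, each fully
#' analysed: PCA component count of the STN slow variable with the colour
#' category, and (optionally) the first-return-map transition rates with the
#' experiment-match flag. Per-cell seeds are derived deterministically from
#' `seed` and the cell index, so interrupted sweeps resume identically.
#'
#' @param g_syn,i_app Parameter pair; alternatively give `preset` (a name
#'   from [sweep_presets()]).
#' @param preset Optional preset name overriding `g_syn`/`i_app`.
#' @param mode Input mode: `"sine"`, `"noisy_sine"`, or `"phase_derived"`
#'   (the latter drives each cell with a surrogate cortical signal peaking at
#'   the cell's frequency).
#' @param amplitudes,frequencies Grid axes (model current units; Hz).
#' @param duration,transient,dt,record_dt Per-cell integration settings (ms);
#'   `NULL` takes configured values.
#' @param replicates Simulations per cell (distinct seeds); the component
#'   count is aggregated by median, rates by mean, the match flag by
#'   majority.
#' @param seed Base seed.
#' @param config Configuration list.
#' @param rates Compute transition rates per cell (slightly slower).
#' @param out Optional CSV path: each completed cell is appended immediately
#'   and existing rows are not recomputed (resume support).
#' @param progress Print one line per cell.
#' @param early_stop_count Optional component-count target: within each
#'   frequency column, once a cell reaches a (median) count at or below this
#'   value, higher amplitudes are skipped (`skipped = TRUE`, counts `NA`).
#'   Minimal-amplitude curves for any target at or above this value are
#'   unaffected, because the skipped cells lie strictly above the smallest
#'   achieving amplitude.
#' @return A `sweep_grid` tibble: one row per cell with `g_syn`, `i_app`,
#'   `mode`, `A`, `omega0`, `component_count`, `category`, `matched`,
#'   `rate_1..rate_4`, `failed`, `skipped`, `cell_seed`.
#' @export
run_sweep <- function(g_syn = NULL, i_app = NULL, preset = NULL,
                      mode = c("sine", "noisy_sine", "phase_derived"),
                      amplitudes = 0:16, frequencies = 10:30,
                      duration = NULL, transient = NULL, dt = NULL,
                      record_dt = NULL, replicates = 1L, seed = 1L,
                      config = default_config(), rates = TRUE, out = NULL,
                      progress = FALSE, early_stop_count = NULL) {
  mode <- match.arg(mode)
  if (!is.null(preset)) {
    pr <- sweep_presets()
    row <- pr[pr$preset == preset, ]
    if (nrow(row) != 1L) stop("unknown preset '", preset, "'")
    g_syn <- row$g_syn; i_app <- row$i_app
  }
  if (is.null(g_syn) || is.null(i_app)) stop("give g_syn and i_app, or a preset")
  if (is.unsorted(amplitudes, strictly = TRUE) ||
      is.unsorted(frequencies, strictly = TRUE)) {
    stop("grid axes must be strictly increasing")
  }
  cells <- tidyr::expand_grid(omega0 = frequencies, A = amplitudes)

  done <- NULL
  if (!is.null(out) && file.exists(out)) {
    done <- utils::read.csv(out)
  }
  res <- vector("list", nrow(cells))
  satisfied_at <- NA_real_
  last_w0 <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    A <- cells$A[ci]; w0 <- cells$omega0[ci]
    if (!identical(w0, last_w0)) {
      satisfied_at <- NA_real_
      last_w0 <- w0
    }
    if (!is.null(done)) {
      hit <- done[done$A == A & done$omega0 == w0, , drop = FALSE]
      if (nrow(hit) >= 1L) {
        res[[ci]] <- tibble::as_tibble(hit[1L, ])
        next
      }
    }
    if (!is.na(satisfied_at)) {
      res[[ci]] <- skipped_cell(g_syn, i_app, mode, A, w0,
                                seed + 1000L * (ci - 1L))
      next
    }
    row <- sweep_cell(g_syn, i_app, mode, A, w0, duration, transient, dt,
                      record_dt, replicates,
                      cell_seed = seed + 1000L * (ci - 1L),
                      config = config, rates = rates)
    if (!is.null(early_stop_count) && !is.na(row$component_count) &&
        row$component_count <= early_stop_count) {
      satisfied_at <- A
    }
    res[[ci]] <- row
    if (!is.null(out)) {
      utils::write.table(row, out, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out), append = file.exists(out))
    }
    if (progress) {
      message(sprintf("[%3d/%d] A=%2g omega0=%2g -> %s components",
                      ci, nrow(cells), A, w0, row$component_count))
    }
  }
  grid <- dplyr::bind_rows(res)
  structure(grid, class = c("sweep_grid", class(grid)),
            mode = mode, g_syn = g_syn, i_app = i_app, seed = seed,
            replicates = replicates)
}

# One grid cell: `replicates` seeded simulations, aggregated.
sweep_cell <- function(g_syn, i_app, mode, A, w0, duration, transient, dt,
                       record_dt, replicates, cell_seed, config, rates) {
  counts <- rep(NA_integer_, replicates)
  matched <- rep(NA, replicates)
  rmat <- matrix(NA_real_, replicates, 4)
  failed <- FALSE
  for (rep_i in seq_len(replicates)) {
    s <- cell_seed + rep_i - 1L
    ok <- tryCatch({
      inp <- if (A == 0) {
        input_spec("none")
      } else if (mode == "phase_derived") {
        dur_s <- (duration %||% config$integration$duration) / 1000
        src <- synthetic_cortical_signal(peak_freq = w0, duration = dur_s + 2,
                                         sample_rate = 1000, seed = s)
        input_spec("phase_derived", A = A, source_signal = src)
      } else {
        input_spec(mode, A = A, omega0 = w0, seed = s)
      }
      sim <- simulate_network(config, inp, duration = duration,
                              transient = transient, dt = dt,
                              record_dt = record_dt, seed = s,
                              g_syn = g_syn, i_app = i_app)
      counts[rep_i] <- network_synchrony(sim)$component_count
      if (rates) {
        sp <- tryCatch(synchrony_patterns(sim), error = function(e) NULL)
        if (!is.null(sp)) {
          rmat[rep_i, ] <- sp$rates$rate
          matched[rep_i] <- sp$matched
        }
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("cell A=%g omega0=%g replicate %d failed: %s",
                      A, w0, rep_i, conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (!ok) failed <- TRUE
  }
  cc <- if (all(is.na(counts))) NA_integer_
        else as.integer(round(stats::median(counts, na.rm = TRUE)))
  tibble::tibble(
    g_syn = g_syn, i_app = i_app, mode = mode, A = A, omega0 = w0,
    component_count = cc,
    category = if (is.na(cc)) NA_character_ else classify_synchrony(cc),
    matched = if (all(is.na(matched))) NA else mean(matched, na.rm = TRUE) > 0.5,
    rate_1 = mean(rmat[, 1], na.rm = TRUE), rate_2 = mean(rmat[, 2], na.rm = TRUE),
    rate_3 = mean(rmat[, 3], na.rm = TRUE), rate_4 = mean(rmat[, 4], na.rm = TRUE),
    failed = failed, skipped = FALSE, cell_seed = cell_seed
  )
}

skipped_cell <- function(g_syn, i_app, mode, A, w0, cell_seed) {
  tibble::tibble(
    g_syn = g_syn, i_app = i_app, mode = mode, A = A, omega0 = w0,
    component_count = NA_integer_, category = NA_character_, matched = NA,
    rate_1 = NA_real_, rate_2 = NA_real_, rate_3 = NA_real_,
    rate_4 = NA_real_, failed = FALSE, skipped = TRUE, cell_seed = cell_seed
  )
}

#' Minimal input amplitude reaching a synchrony target
#'
#' For each frequency of a sweep grid, the smallest amplitude on the grid
#' whose component count is at or below `target_count` (`NA` when no
#' amplitude achieves it). Targets 3 and 5 correspond to the study's red and
#' green synchrony levels.
#'
#' @param grid A `sweep_grid` from [run_sweep()].
#' @param target_count Component-count target (3 or 5 in the study).
#' @return A `minimal_amplitude_curve` tibble: `omega0`, `min_amplitude`,
#'   `target`.
#' @export
minimal_amplitude <- function(grid, target_count) {
  out <- grid |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$omega0) |>
    dplyr::summarise(min_amplitude = {
      ok <- !is.na(.data$component_count) &
        .data$component_count <= target_count
      if (any(ok)) min(.data$A[ok]) else NA_real_
    }, .groups = "drop") |>
    dplyr::mutate(target = as.integer(target_count)) |>
    dplyr::arrange(.data$omega0)
  structure(out, class = c("minimal_amplitude_curve", class(out)),
            target = as.integer(target_count))
}

#' Tongue-tip frequency of a minimal-amplitude curve
#'
#' The frequency minimizing the minimal amplitude — the tip of the
#' entrainment (Arnold) tongue. Ties over a flat minimum are broken toward
#' the frequency with the deeper local neighbourhood (smallest mean of the
#' curve over the frequency and its defined grid neighbours), then toward
#' the lower frequency.
#'
#' @param curve A `minimal_amplitude_curve` with at least 3 defined
#'   frequencies.
#' @param smooth If `TRUE`, the argmin is taken over the
#'   neighbourhood-averaged curve (moving mean over each frequency and its
#'   defined grid neighbours) instead of the raw curve — appropriate for
#'   locating the centre of a broad, noisy resonance region rather than a
#'   sharp tongue.
#' @return Frequency in Hz.
#' @export
tongue_tip <- function(curve, smooth = FALSE) {
  cv <- curve[!is.na(curve$min_amplitude), ]
  if (nrow(cv) < 3L) stop("curve must have at least 3 defined frequencies")
  if (smooth) {
    step <- min(diff(sort(curve$omega0)))
    sm <- vapply(cv$omega0, function(f) {
      mean(cv$min_amplitude[abs(cv$omega0 - f) <= step + 1e-9])
    }, numeric(1))
    cv$min_amplitude <- sm
  }
  vmin <- min(cv$min_amplitude)
  cand <- cv$omega0[cv$min_amplitude == vmin]
  if (length(cand) == 1L) return(cand)
  step <- min(diff(sort(curve$omega0)))
  nb_mean <- vapply(cand, function(f) {
    w <- abs(cv$omega0 - f) <= step + 1e-9
    mean(cv$min_amplitude[w])
  }, numeric(1))
  cand <- cand[nb_mean == min(nb_mean)]
  min(cand)
}
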