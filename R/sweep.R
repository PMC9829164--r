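#' Enumerate the channel-block / cycle-length sweep grid
#'
#' Deterministic lexicographic enumeration over IKr block fraction, ICaL
#' block fraction and pacing cycle length. The default grid is the full
#' 11 x 11 x 16 factorial: block levels 0, 0.1, ..., 1.0 on both channels
#' (121 dual-block settings) and CL = 250, 300, ..., 1000 ms (16 values;
#' 1936 runs in total).
#'
#' @param s_kr_block IKr block fractions (0 = control, 1 = complete block).
#' @param s_cal_block ICaL block fractions.
#' @param cl Pacing cycle lengths (ms).
#' @param subsample Optionally draw this many random settings from the grid
#'   (with `seed`); `NULL` = full grid.
#' @param seed Seed for `subsample`.
#' @return Object of class `sweep_grid`: a data frame with `run_id`,
#'   `s_kr_block`, `s_cal_block`, `cl`; attribute `n_settings`.
#' @export
#' @examples
#' g <- sweep_grid()
#' attr(g, "n_settings")  # 121
#' nrow(g)                # 1936
sweep_grid <- function(s_kr_block = seq(0, 1, by = 0.1),
                       s_cal_block = seq(0, 1, by = 0.1),
                       cl = seq(250, 1000, by = 50),
                       subsample = NULL, seed = NULL) {
  if (!length(s_kr_block) || !length(s_cal_block) || !length(cl))
    stop("empty sweep axis", call. = FALSE)
  if (any(s_kr_block < 0 | s_kr_block > 1) ||
      any(s_cal_block < 0 | s_cal_block > 1))
    stop("block fractions must lie in [0, 1]", call. = FALSE)
  if (any(cl <= 0)) stop("cycle lengths must be positive", call. = FALSE)
  g <- expand.grid(cl = sort(cl), s_cal_block = sort(s_cal_block),
                   s_kr_block = sort(s_kr_block),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("s_kr_block", "s_cal_block", "cl")]
  g <- g[order(g$s_kr_block, g$s_cal_block, g$cl), ]
  if (!is.null(subsample)) {
    if (!is.null(seed)) set.seed(seed)
    g <- g[sort(sample.int(nrow(g), subsample)), ]
  }
  rownames(g) <- NULL
  g$run_id <- sprintf("kr%03.0f_cal%03.0f_cl%04d", 100 * g$s_kr_block,
                      100 * g$s_cal_block, g$cl)
  g <- g[, c("run_id", "s_kr_block", "s_cal_block", "cl")]
  structure(g, class = c("sweep_grid", "data.frame"),
            n_settings = length(unique(paste(g$s_kr_block, g$s_cal_block))))
}

# polynomial rolling hash over the serialized object (double-precision safe);
# cheap provenance fingerprint
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 68719476731   # prime < 2^36
  sprintf("%011.0f", h)
}

# analyse one simulated run into a one-row record
.analyze_run <- function(result, control_qt, th) {
  cls <- classify_run(result, control_qt = control_qt, th = th)
  feats <- lapply(beat_windows(result)$beat, function(b)
    compute_qt_tpe(result, b, v_rep = th$v_rep))
  nb <- length(feats)
  ev <- cls$events
  subtype <- NA_character_; ead_cv <- NA_real_
  if (cls$category == "ead") {
    sp <- classify_spatial_pattern(ev, result, th)
    subtype <- sp$subtype; ead_cv <- sp$ead_cv
  }
  data.frame(
    category = cls$category, ead_subtype = subtype, ead_cv = ead_cv,
    n_ead_events = if (is.null(ev)) 0L else nrow(ev),
    alternans_type = if (is.null(cls$alternans)) NA_character_
                     else cls$alternans$type,
    qt_1 = feats[[max(1, nb - 1)]]$qt, qt_2 = feats[[nb]]$qt,
    t_pe_1 = feats[[max(1, nb - 1)]]$t_pe, t_pe_2 = feats[[nb]]$t_pe,
    stringsAsFactors = FALSE)
}

#' Run the full parameter-space sweep
#'
#' For every `(s_kr_block, s_cal_block, cl)` triple: build the strand with
#' the corresponding [channel_scaling()], simulate the pacing protocol,
#' extract beat features, detect EADs and classify the run. Control
#' references (QT per CL) are computed first from the control scaling.
#' Failed runs are recorded with category `"numeric_failure"`, never
#' dropped. Output row order follows the grid; reruns with an identical
#' configuration are bit-identical (per-run determinism plus ordered
#' reduction), which the provenance hash witnesses.
#'
#' @param grid A [sweep_grid()].
#' @param config Strand [tissue_config()] template (its scaling is replaced
#'   per run).
#' @param n_beats,record_last Pacing protocol (per-CL protocols are built
#'   from these).
#' @param output_dt Output sampling (ms).
#' @param workers Parallel workers (forked; output order is independent of
#'   scheduling). Default 1.
#' @param conditioning_beats Single-cell pre-pacing beats: before each strand
#'   run, every cell is initialised from its cell type's paced single-cell
#'   steady state at the run's cycle length and scaling (isolated cells are
#'   cheap to pace, and the coupled strand then settles within a few beats;
#'   without this, slow gating pools still drift after ten strand beats at
#'   long cycle lengths and the drift masquerades as alternans).
#' @param th Thresholds from [analysis_thresholds()].
#' @param keep_results Keep the per-run `pvs_simulation` objects (memory!).
#' @param verbose Print per-run progress to stderr.
#' @return Object of class `pvs_sweep`: the grid with one result record per
#'   triple, attributes `control` (per-CL reference table) and
#'   `provenance`.
#' @export
run_sweep <- function(grid, config = tissue_config(cells_per_layer = 10),
                      n_beats = 10, record_last = 2, output_dt = 0.5,
                      workers = 1, conditioning_beats = 20,
                      th = analysis_thresholds(),
                      keep_results = FALSE, verbose = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(config, "tissue_config"))
  types <- rep(config$layer_order, each = config$cells_per_layer)
  run_one <- function(skr_b, scal_b, cl) {
    sc <- channel_scaling(s_kr = 1 - skr_b, s_cal = 1 - scal_b)
    tis <- build_tissue(config, scaling = sc)
    state0 <- NULL
    if (conditioning_beats > 0) {
      cond <- lapply(config$layer_order, function(ty)
        run_cell(make_cell(ty, sc),
                 pacing_protocol(cl, n_beats = conditioning_beats,
                                 record_last = 1),
                 stim_amplitude = config$stim_amplitude,
                 stim_duration = config$stim_duration)$final_state[, 1])
      names(cond) <- config$layer_order
      state0 <- vapply(types, function(ty) cond[[ty]],
                       numeric(length(.STATE_NAMES)))
    }
    simulate_tissue(tis, pacing_protocol(cl, n_beats, record_last),
                    output_dt = output_dt, state0 = state0)
  }
  cls <- sort(unique(grid$cl))
  control <- do.call(rbind, lapply(cls, function(cl) {
    res <- run_one(0, 0, cl)
    cr <- control_reference(res)
    data.frame(cl = cl, qt = cr$qt, t_peak_amp = cr$t_peak_amp,
               t_halfmax_width = cr$t_halfmax_width)
  }))
  worker <- function(k) {
    row <- grid[k, ]
    rec <- tryCatch({
      res <- run_one(row$s_kr_block, row$s_cal_block, row$cl)
      out <- .analyze_run(res, control$qt[control$cl == row$cl], th)
      if (keep_results) attr(out, "result") <- res
      out
    }, error = function(e) data.frame(
      category = "numeric_failure", ead_subtype = NA_character_,
      ead_cv = NA_real_, n_ead_events = NA_integer_,
      alternans_type = NA_character_, qt_1 = NA_real_, qt_2 = NA_real_,
      t_pe_1 = NA_real_, t_pe_2 = NA_real_, stringsAsFactors = FALSE))
    if (verbose) message(sprintf("[%d/%d] %s -> %s", k, nrow(grid),
                                 row$run_id, rec$category))
    rec
  }
  recs <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(grid)), worker, mc.cores = workers)
  } else lapply(seq_len(nrow(grid)), worker)
  res_attr <- if (keep_results) lapply(recs, attr, "result") else NULL
  out <- cbind(as.data.frame(grid), do.call(rbind, lapply(recs, function(r) {
    attr(r, "result") <- NULL; r
  })))
  structure(out, class = c("pvs_sweep", "data.frame"),
            control = control,
            results = res_attr,
            provenance = list(
              config_hash = config_hash(list(grid = as.data.frame(grid),
                                             config = config,
                                             n_beats = n_beats,
                                             record_last = record_last,
                                             output_dt = output_dt, th = th)),
              package_version = as.character(utils::packageVersion("pvscable"))))
}

#' @export
print.pvs_sweep <- function(x, ...) {
  cat(sprintf("<pvs_sweep> %d runs; categories: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$category)),
                            table(x$category)), collapse = ", ")))
  invisible(as.data.frame(x))
}
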