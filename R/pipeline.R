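#' Assemble a pipeline run configuration
#'
#' One object drives a full run: acquire (or synthesize) a sequence, align
#' it, optionally segment it, measure every polyline region on every frame,
#' and summarize the dynamics. Paths referenced by the configuration are
#' checked up front, before any computation.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed recorded in the manifest and used to derive all
#'   stage seeds.
#' @param input Path to a TIFF stack or PNG directory (mutually exclusive
#'   with `synth`).
#' @param synth List with `spec` ([scene_spec()]), `motion`
#'   ([motion_track()]) and `dilation` ([dilation_track()]) for a fully
#'   synthetic run.
#' @param t_min Per-frame acquisition times in minutes; frames at
#'   `t_min <= 0` are pre-stimulus (the last of them is the control), frames
#'   at `t_min > 0` are post-stimulus. Default: frame 1 at 0, then 1, 2, ...
#' @param mm_per_px Calibration for file-based input.
#' @param stabilization List: `enabled`, `block` (a [roi()]; `NULL`
#'   auto-places a box on the scene fiducial), `search_radius`.
#' @param segmentation List: `use_mask` (feed the calliper the CNN-masked
#'   image, the default, rather than the raw aligned frame), `weights`
#'   (optional JSON path of a trained network), `config` (a
#'   [segnet_config()]), `train` (synthetic-training options: `n_pairs`,
#'   `dilation_range`, `jitter_px`, `noise_sigma`).
#' @param calliper List: `polylines` (JSON path or named list of
#'   [polyline()]; `NULL` uses the synthetic vessel centerlines), `spacing`,
#'   `half_length`, `contrast_floor`.
#' @param dynamics List: `final_time` (defaults to the last post-stimulus
#'   frame time).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input = NULL, synth = NULL,
                       t_min = NULL, mm_per_px = 0.1,
                       stabilization = list(), segmentation = list(),
                       calliper = list(), dynamics = list()) {
  stabilization <- modifyList(
    list(enabled = TRUE, block = NULL, search_radius = 15), stabilization
  )
  segmentation <- modifyList(
    list(
      use_mask = TRUE, weights = NULL, config = NULL,
      train = list(
        n_pairs = 16, dilation_range = c(0.9, 1.6), jitter_px = 5,
        noise_sigma = 2
      )
    ),
    segmentation
  )
  calliper <- modifyList(
    list(polylines = NULL, spacing = 2, half_length = 15, contrast_floor = 5),
    calliper
  )
  dynamics <- modifyList(list(final_time = NULL), dynamics)
  if (is.null(input) == is.null(synth)) {
    abort("Exactly one of `input` and `synth` must be given.")
  }
  if (!is.null(input) && !file.exists(input) && !dir.exists(input)) {
    abort(sprintf("Input sequence '%s' does not exist.", input))
  }
  if (is.character(calliper$polylines) && !file.exists(calliper$polylines)) {
    abort(sprintf("Polyline file '%s' does not exist.", calliper$polylines))
  }
  if (!is.null(segmentation$weights) && !file.exists(segmentation$weights)) {
    abort(sprintf("Weights file '%s' does not exist.", segmentation$weights))
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), input = input,
      synth = synth, t_min = t_min, mm_per_px = mm_per_px,
      stabilization = stabilization, segmentation = segmentation,
      calliper = calliper, dynamics = dynamics
    ),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

# Synthetic image/mask training pairs spanning the dilation range the
# pipeline must measure, with translational jitter and noise.
synth_training_pairs <- function(spec, n_pairs, dilation_range, jitter_px,
                                 noise_sigma, seed) {
  spec$noise_sigma <- noise_sigma
  with_seed(seed, {
    scales <- runif(n_pairs, dilation_range[1], dilation_range[2])
    jit <- matrix(runif(2 * n_pairs, -jitter_px, jitter_px), ncol = 2)
    seeds <- sample.int(1e6, n_pairs)
    pairs <- purrr::map(seq_len(n_pairs), function(i) {
      render_frame(spec,
        dilation_scale = scales[i], translation = jit[i, ],
        rng_seed = seeds[i]
      )
    })
    list(
      images = purrr::map(pairs, "image"),
      masks = purrr::map(pairs, "mask")
    )
  })
}

#' Run the full vein-dynamics pipeline
#'
#' Executes align -> (optional) segment -> measure-per-frame -> dynamics and
#' writes, under `cfg$out_dir`: `diameters.csv` (per region and frame),
#' `offsets.csv` (stabilization motion estimates), `dynamics.json`
#' (percent dilation, decay fits and diameter-temperature context per
#' region), `qc.json` (profile-uniformity dispersion before/after
#' alignment), `masks/frame_NNN.png` (when segmenting), and `manifest.json`
#' (configuration hash + seed). Any stage failure aborts with the stage
#' name.
#'
#' @param cfg A [run_config()].
#' @return A list with `diameters` (tibble), `dynamics` (list), `motion`
#'   (tibble), `qc` (list), `manifest` (list), invisibly also written to
#'   disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  seq <- run_stage("acquire", {
    if (!is.null(cfg$synth)) {
      render_sequence(cfg$synth$spec, cfg$synth$motion, cfg$synth$dilation)
    } else {
      read_sequence(cfg$input, mm_per_px = cfg$mm_per_px)
    }
  })
  n <- length(seq$frames)
  t_min <- cfg$t_min %||% c(0, seq_len(n - 1))
  if (length(t_min) != n) abort("`t_min` must have one entry per frame.")

  align <- run_stage("stabilize", {
    if (!cfg$stabilization$enabled) {
      list(
        aligned = seq,
        motion = tibble::tibble(
          frame = seq_len(n), dy = 0L, dx = 0L, sad = 0, degenerate = FALSE
        )
      )
    } else {
      block <- cfg$stabilization$block
      if (is.null(block)) {
        fid <- seq$spec$fiducial
        if (is.null(fid)) {
          abort("No stabilization block given and the scene has no fiducial.")
        }
        half <- ceiling(fid$radius) + 6L
        block <- roi(
          round(fid$center[1]) - half, round(fid$center[2]) - half,
          2L * half + 1L, 2L * half + 1L
        )
      }
      align_sequence(seq, block, search_radius = cfg$stabilization$search_radius)
    }
  })
  qc <- run_stage("qc", {
    if (cfg$stabilization$enabled && !is.null(cfg$stabilization$block %||% seq$spec$fiducial)) {
      block <- cfg$stabilization$block
      if (is.null(block)) {
        fid <- seq$spec$fiducial
        half <- ceiling(fid$radius) + 6L
        block <- roi(
          round(fid$center[1]) - half, round(fid$center[2]) - half,
          2L * half + 1L, 2L * half + 1L
        )
      }
      list(
        dispersion_raw = profile_uniformity(seq, block)$dispersion,
        dispersion_aligned = profile_uniformity(align$aligned, block)$dispersion
      )
    } else {
      list(dispersion_raw = NA_real_, dispersion_aligned = NA_real_)
    }
  })

  model <- NULL
  measured_frames <- align$aligned$frames
  if (isTRUE(cfg$segmentation$use_mask)) {
    model <- run_stage("segment-train", {
      if (!is.null(cfg$segmentation$weights)) {
        load_segnet(cfg$segmentation$weights)
      } else {
        if (is.null(seq$spec)) {
          abort("Training needs a synthetic scene; give pretrained `weights` for file input.")
        }
        seg_cfg <- cfg$segmentation$config %||%
          segnet_config(input_size = nrow(seq$frames[[1]]), seed = cfg$seed)
        tr <- cfg$segmentation$train
        pairs <- synth_training_pairs(
          seq$spec, tr$n_pairs, tr$dilation_range, tr$jitter_px,
          tr$noise_sigma,
          seed = cfg$seed + 17L
        )
        train_segnet(build_segnet(seg_cfg), pairs$images, pairs$masks)$model
      }
    })
    measured_frames <- run_stage("segment-predict", {
      dir.create(file.path(cfg$out_dir, "masks"), showWarnings = FALSE)
      purrr::imap(align$aligned$frames, function(fr, k) {
        pred <- predict_mask(model, fr, image_id = sprintf("frame_%03d", k))
        write_mask_png(
          pred$mask,
          file.path(cfg$out_dir, "masks", sprintf("frame_%03d.png", k))
        )
        masked_image(pred, background = max(fr))
      })
    })
  }

  regions <- run_stage("regions", {
    pl <- cfg$calliper$polylines
    if (is.character(pl)) {
      read_polylines(pl)
    } else if (is.list(pl) && length(pl) > 0) {
      pl
    } else if (!is.null(seq$spec)) {
      rs <- purrr::map(seq$spec$vessels, function(v) polyline(v$centerline))
      names(rs) <- paste0("vessel", seq_along(rs))
      rs
    } else {
      abort("No polylines given and no synthetic ground truth available.")
    }
  })

  diameters <- run_stage("measure", {
    rows <- purrr::imap(regions, function(line, id) {
      purrr::map(seq_len(n), function(k) {
        m <- measure_region(
          measured_frames[[k]], line,
          spacing = cfg$calliper$spacing,
          half_length = cfg$calliper$half_length,
          mm_per_px = seq$mm_per_px,
          contrast_floor = cfg$calliper$contrast_floor,
          region_id = id
        )
        dplyr::mutate(dplyr::select(m, -"slices"),
          frame = k, t_min = t_min[k], .after = "region"
        )
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })

  dyn <- run_stage("dynamics", {
    purrr::imap(regions, function(line, id) {
      d <- dplyr::filter(diameters, .data$region == id)
      base <- dplyr::filter(d, .data$t_min <= 0)
      post <- dplyr::filter(d, .data$t_min > 0)
      out <- list(region = id)
      if (nrow(base) > 0 && nrow(post) > 0) {
        pdv <- percent_dv(post$mean_mm, tail(base$mean_mm, 1))
        out$percent_dv <- pdv$percent_dv
        out$increment_pct <- pdv$increment_pct
      }
      if (nrow(post) >= 4) {
        fit <- tryCatch(fit_decay(post$t_min, post$mean_mm), error = function(e) NULL)
        if (!is.null(fit) && !fit$degenerate) {
          out$decay <- list(
            a = fit$a, tau = fit$tau, c = fit$c, r_squared = fit$r_squared
          )
        }
      }
      out
    })
  })

  manifest <- list(
    package = "veindyn",
    version = as.character(utils::packageVersion("veindyn")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    n_frames = n,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  run_stage("write", {
    readr::write_csv(diameters, file.path(cfg$out_dir, "diameters.csv"))
    readr::write_csv(align$motion, file.path(cfg$out_dir, "offsets.csv"))
    jsonlite::write_json(dyn, file.path(cfg$out_dir, "dynamics.json"),
      auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(qc, file.path(cfg$out_dir, "qc.json"),
      auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  })
  invisible(list(
    diameters = diameters, dynamics = dyn, motion = align$motion,
    qc = qc, manifest = manifest, model = model
  ))
}
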