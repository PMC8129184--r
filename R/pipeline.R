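#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

write_sidecar <- function(out_dir, command, inputs, params, seed, artifacts) {
  side <- file.path(out_dir, paste0(command, ".provenance.json"))
  jsonlite::write_json(
    list(command = command, inputs = inputs, parameters = params,
         seed = seed, artifacts = basename(artifacts),
         package = "braincalib",
         version = as.character(utils::packageVersion("braincalib"))),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  side
}

require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
}

#' Run one pipeline stage
#'
#' Dispatches the named pipeline stage, writes its artifacts under `out_dir`
#' together with a JSON provenance sidecar (inputs, parameters, seed,
#' package version). On error any partially written artifacts are removed.
#'
#' Commands: `fit-prony` (tan-delta CSV to Prony JSON), `build-heterogeneity`
#' (stiffness NIfTI to card-set JSON + label NIfTI), `simulate-phantom`
#' (synthetic phantom simulation to per-receiver CSVs), `rate` (manifest of
#' reference/test CSVs to a rating JSON), `calibrate` (synthetic bundle to a
#' calibration report JSON), `strain-metrics` (4D displacement NIfTI +
#' region labels to a metrics CSV), `make-fixtures` (deterministic synthetic
#' fixture set).
#'
#' @param command One of the commands listed above.
#' @param config Named list of stage parameters (see Details of each stage
#'   function), or a YAML path read with [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the sidecar and used for any
#'   randomness (default taken from `config$seed`, else 1).
#' @return Character vector of artifact paths, invisibly.
#' @export
pipeline_run <- function(command, config = list(), out_dir = ".",
                         seed = config$seed %||% 1L) {
  command <- match.arg(command, c("fit-prony", "build-heterogeneity",
                                  "simulate-phantom", "rate", "calibrate",
                                  "strain-metrics", "make-fixtures"))
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  run <- switch(command,
    "fit-prony" = function() {
      require_inputs(config$input)
      dat <- utils::read.csv(config$input)
      pr <- fit_prony(dat, n_terms = config$n_terms %||% 4,
                      tau_grid = config$tau_grid %||% c(10, 1, 0.1, 0.01))
      out <- note(file.path(out_dir, "prony.json"))
      jsonlite::write_json(list(g = pr$g, tau_ms = pr$tau, g_inf = pr$g_inf),
                           out, auto_unbox = TRUE, digits = NA)
      list(inputs = config$input, params = config[setdiff(names(config), "input")])
    },
    "build-heterogeneity" = function() {
      require_inputs(config$mre)
      vol <- read_stiffness_volume(config$mre, absent = config$absent %||% "nan")
      norm <- truncate_and_normalize(vol, low_pct = config$low_pct %||% 15,
                                     high_pct = config$high_pct %||% 98)
      labels <- bin_relative_stiffness(norm, n_bins = config$bins %||% 10)
      cards <- build_material_cards(labels, config$mu0_med %||% 1.125,
                                    config$alpha %||% 6.67, brain_prony())
      write_material_card_set(cards, note(file.path(out_dir, "cards.json")))
      write_labels_volume(labels, note(file.path(out_dir, "labels.nii.gz")))
      note(file.path(out_dir, "labels.nii.gz.json"))
      list(inputs = config$mre, params = config[setdiff(names(config), "mre")])
    },
    "simulate-phantom" = function() {
      case <- default_case_matrix()
      case <- case[case$case_id == (config$case %||% "z-20-60"), ]
      if (nrow(case) != 1) stop("unknown case id: ", config$case, call. = FALSE)
      ph <- phantom_config(n_nodes = config$n_nodes %||% 150,
                           n_receivers = config$n_receivers %||% 12, seed = seed)
      cards <- build_material_cards(ph$labels$centers, config$mu0_med %||% 1.125,
                                    config$alpha %||% 6.67, brain_prony())
      sim <- simulate_phantom(ph, make_pulse(case$axis, case$peak_rad_s,
                                             case$duration_ms), cards,
                              duration_ms = config$duration_ms %||% 200)
      for (rid in unique(sim$receiver)) {
        f <- note(file.path(out_dir, sprintf("receiver_%s.csv", rid)))
        utils::write.csv(sim[sim$receiver == rid,
                             c("time_ms", "x_mm", "y_mm", "z_mm")],
                         f, row.names = FALSE)
      }
      list(inputs = NULL, params = config)
    },
    "rate" = function() {
      require_inputs(config$manifest)
      man <- jsonlite::read_json(config$manifest, simplifyVector = TRUE)
      base <- dirname(config$manifest)
      recs <- lapply(seq_len(nrow(man$receivers)), function(i) {
        rf <- file.path(base, man$receivers$reference[i])
        tf <- file.path(base, man$receivers$test[i])
        require_inputs(c(rf, tf))
        receiver_record(man$receivers$id[i], utils::read.csv(rf),
                        utils::read.csv(tf))
      })
      res <- weighted_overall(recs)
      out <- note(file.path(out_dir, "rating.json"))
      jsonlite::write_json(list(wccora = res$wccora, receivers = res$ratings),
                           out, auto_unbox = TRUE, digits = NA)
      list(inputs = config$manifest, params = config)
    },
    "calibrate" = function() {
      dur <- config$duration_ms %||% 200
      bundle <- make_dataset(
        true_mu0_med = config$true_mu0_med %||% 1.125,
        true_alpha = config$true_alpha %||% 6.67,
        noise_sd_mm = config$noise_sd_mm %||% 0,
        n_subjects = config$n_subjects %||% 3,
        cases = config$cases %||% c("z-20-60", "x-40-30"),
        n_nodes = config$n_nodes %||% 150,
        n_receivers = config$n_receivers %||% 12,
        duration_ms = dur,
        seed = seed)
      cfg <- calibration_config(duration_ms = dur, seed = seed)
      s1 <- calibrate_stage1(bundle, cfg)
      s2 <- calibrate_stage2(bundle, s1$mu0_med, cfg)
      out <- note(file.path(out_dir, "report.json"))
      jsonlite::write_json(
        list(mu0_med_kpa = s1$mu0_med, alpha = s2$alpha,
             stage1 = glance(s1$search), stage2 = glance(s2$search),
             provenance = bundle$provenance),
        out, auto_unbox = TRUE, digits = NA, null = "null")
      list(inputs = NULL, params = config)
    },
    "strain-metrics" = function() {
      require_inputs(c(config$disp, config$labels))
      img <- RNifti::readNifti(config$disp)
      u <- array(as.numeric(img), dim(img))
      lab <- RNifti::readNifti(config$labels)
      labels <- array(as.integer(lab), dim(lab)[1:3])
      labels[labels == 0L] <- NA_integer_
      field <- displacement_field(u, spacing = RNifti::pixdim(img)[1:3])
      met <- regional_summary(strain_from_displacement(field), labels,
                              threshold = config$threshold %||% 0.02)
      utils::write.csv(met, note(file.path(out_dir, "metrics.csv")),
                       row.names = FALSE)
      list(inputs = c(config$disp, config$labels), params = config)
    },
    "make-fixtures" = function() {
      mre <- generate_synthetic_mre(shape = config$shape %||% c(24, 24, 24),
                                    seed = seed)
      write_stiffness_volume(mre, note(file.path(out_dir, "synthetic_mre.nii.gz")))
      pr <- brain_prony()
      f <- 10^seq(-1, 3, length.out = 25)
      utils::write.csv(data.frame(freq_hz = f, tan_delta = tan_delta(f, pr)),
                       note(file.path(out_dir, "tan_delta.csv")), row.names = FALSE)
      ph <- phantom_config(n_nodes = config$n_nodes %||% 40, n_receivers = 4,
                           seed = seed)
      cards <- build_material_cards(ph$labels$centers, 1.125, 6.67, pr)
      sim <- simulate_phantom(ph, make_pulse("z", 20, 60), cards,
                              duration_ms = config$duration_ms %||% 100)
      ids <- unique(sim$receiver)
      for (rid in ids) {
        fcsv <- note(file.path(out_dir, sprintf("receiver_%s.csv", rid)))
        utils::write.csv(sim[sim$receiver == rid,
                             c("time_ms", "x_mm", "y_mm", "z_mm")],
                         fcsv, row.names = FALSE)
      }
      man <- note(file.path(out_dir, "manifest.json"))
      jsonlite::write_json(
        list(case = "z-20-60", axis = "z", peak_rad_s = 20, duration_ms = 60,
             receivers = data.frame(
               id = ids,
               reference = sprintf("receiver_%s.csv", ids),
               test = sprintf("receiver_%s.csv", ids))),
        man, auto_unbox = TRUE, digits = NA)
      list(inputs = NULL, params = config)
    })
  res <- tryCatch(run(), error = function(e) {
    unlink(written)
    stop("pipeline stage '", command, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  side <- write_sidecar(out_dir, command, res$inputs, res$params, seed, written)
  invisible(c(written, side))
}
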