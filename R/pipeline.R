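# End-to-end pipeline: simulate a cohort, build correlation-map series,
# detect peaks, run MPCA, cluster the flavonol table, and write every
# intermediate plus a checksum manifest. Re-running with the same config
# and seed is bit-identical.

#' Default pipeline configuration
#'
#' Flat named list covering the whole chain; see the field names in the
#' returned list. Amend with [modifyList()] or load overrides from a
#' `key: value` text file via [read_run_config()].
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid_start = 245, grid_stop = 410, grid_step = 1,
    n_authentic = 0L, n_rutin_adulterated = 0L,
    n_quercetin_adulterated = 0L,
    n_quercetin_kaempferol_adulterated = 0L, n_no_ginkgo = 0L,
    noise_sigma = 0.002, jitter = 0.15,
    series = "A",                     # comma-separated subset of A,B,C
    peak_rel_threshold = 0.10, peak_min_offdiag = 5, peak_merge_radius = 4,
    mpca_components = 3L, cv_splits = 10L, cv_per_blind = 2L,
    cv_order = "blocked", autoscale_offset = 1e-5,
    run_cv = FALSE, run_hca = FALSE, hca_k = 4L
  )
}

#' Read pipeline configuration overrides from a key: value text file
#'
#' Lines of the form `key: value`; `#` comments and blank lines ignored.
#' Values are coerced to the type of the corresponding default.
#'
#' @param path Config file path.
#' @param base Base configuration to override (default [default_config()]).
#' @return Full configuration list.
#' @export
read_run_config <- function(path, base = default_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("bad config line: '", ln, "'")
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (!key %in% names(base)) stop("unknown config key: '", key, "'")
    base[[key]] <- if (is.numeric(base[[key]])) {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) stop("non-numeric value for key '", key, "'")
      if (is.integer(base[[key]])) as.integer(v) else v
    } else if (is.logical(base[[key]])) {
      toupper(val) %in% c("TRUE", "T", "YES", "1")
    } else val
  }
  base
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' Stages, in order: simulate the cohort; for each requested series build
#' the asynchronous map stack and write the per-product maps; detect and
#' write cross peaks; fit MPCA (scores, explained variance, RMSEC,
#' optionally venetian-blinds RMSECV); optionally cluster the generated
#' flavonol table. Writes a `manifest.txt` recording the config, seed and
#' an md5 checksum of every artifact.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage progress lines.
#' @return Invisibly, a list with the cohort, per-series stacks/models/
#'   peak tables, the HCA result (if run), and the manifest path.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  stopifnot(is.list(config))
  config <- utils::modifyList(default_config(), config)
  series <- toupper(trimws(strsplit(config$series, ",")[[1]]))
  if (!length(series) || !all(series %in% c("A", "B", "C"))) {
    stop("config series must name a subset of A,B,C")
  }
  counts <- c(
    authentic = config$n_authentic,
    rutin_adulterated = config$n_rutin_adulterated,
    quercetin_adulterated = config$n_quercetin_adulterated,
    quercetin_kaempferol_adulterated =
      config$n_quercetin_kaempferol_adulterated,
    no_ginkgo = config$n_no_ginkgo)
  if (sum(counts) == 0L) stop("configuration requests an empty cohort")
  note <- function(...) if (!quiet) message("[ginkgocos] ", sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(p) { artifacts[[length(artifacts) + 1L]] <<- p; p }

  grid <- wl_grid(config$grid_start, config$grid_stop, config$grid_step)
  note("simulate: %d products, noise %.4g, seed %d",
       sum(counts), config$noise_sigma, config$seed)
  cohort <- simulate_cohort(counts[counts > 0], seed = config$seed,
                            noise_sigma = config$noise_sigma,
                            jitter = config$jitter, grid = grid)
  for (p in cohort$products) {
    add(write_spectrum(p$pair$methanol,
                       file.path(out_dir, paste0(p$product_id, "_meoh.csv"))))
    add(write_spectrum(p$pair$water,
                       file.path(out_dir, paste0(p$product_id, "_water.csv"))))
  }
  add(write_csv_plain(cohort$flavonol_table,
                      file.path(out_dir, "flavonol_table.csv")))
  add(write_csv_plain(
    data.frame(product_id = cohort$flavonol_table$product_id,
               archetype = cohort$flavonol_table$archetype),
    file.path(out_dir, "labels.csv")))

  out <- list(cohort = cohort, series = list(), manifest = NULL)
  for (sr in series) {
    note("series %s: building %d asynchronous maps", sr, sum(counts))
    stack <- build_series(cohort, sr)
    for (i in seq_along(stack$maps)) {
      add(write_map(stack$maps[[i]],
                    file.path(out_dir, sprintf("map_%s_%s.csv", sr,
                                               stack$sample_ids[i]))))
    }
    peaks <- do.call(rbind, lapply(seq_along(stack$maps), function(i) {
      pk <- detect_cross_peaks(stack$maps[[i]],
                               rel_threshold = config$peak_rel_threshold,
                               min_offdiag = config$peak_min_offdiag,
                               merge_radius = config$peak_merge_radius)
      if (nrow(pk)) cbind(product_id = stack$sample_ids[i], pk)
      else NULL
    }))
    if (is.null(peaks) || nrow(peaks) == 0L) {
      peaks <- data.frame(product_id = character(0), nu1 = numeric(0),
                          nu2 = numeric(0), magnitude = numeric(0),
                          sign = character(0))
    }
    note("series %s: %d cross peaks", sr, nrow(peaks))
    add(write_csv_plain(peaks, file.path(out_dir,
                                         sprintf("peaks_%s.csv", sr))))
    model <- NULL
    cv <- NULL
    n <- length(stack$maps)
    kmax <- min(config$mpca_components, n - 1L)
    if (kmax >= 1L && n >= 2L) {
      model <- mpca(stack, k_max = kmax, offset = config$autoscale_offset)
      sc <- data.frame(product_id = rownames(model$scores), model$scores)
      names(sc)[-1] <- paste0("PC", seq_len(kmax))
      add(write_csv_plain(sc, file.path(out_dir,
                                        sprintf("scores_%s.csv", sr))))
      add(write_csv_plain(
        data.frame(component = seq_len(kmax),
                   explained_variance_pct = model$explained_variance_pct,
                   cumulative_pct = model$cumulative_variance_pct,
                   rmsec = model$rmsec_per_k),
        file.path(out_dir, sprintf("variance_%s.csv", sr))))
      if (isTRUE(config$run_cv) && n >= config$cv_splits) {
        cv <- mpca_cross_validate(unfold(stack), kmax,
                                  n_splits = config$cv_splits,
                                  per_blind = config$cv_per_blind,
                                  order = config$cv_order,
                                  offset = config$autoscale_offset)
        add(write_csv_plain(
          data.frame(component = seq_len(kmax),
                     rmsecv = cv$rmsecv_per_k),
          file.path(out_dir, sprintf("rmsecv_%s.csv", sr))))
      }
      note("series %s: MPCA cumulative variance %.2f%% at %d PCs",
           sr, model$cumulative_variance_pct[kmax], kmax)
    }
    out$series[[sr]] <- list(stack = stack, peaks = peaks,
                             model = model, cv = cv)
  }
  if (isTRUE(config$run_hca)) {
    note("hca: Ward/Euclidean on generated flavonol table, k = %d",
         config$hca_k)
    out$hca <- hca_flavonols(cohort$flavonol_table[
      c("product_id", flavonol_cols)], k = config$hca_k)
    add(write_csv_plain(out$hca$partition,
                        file.path(out_dir, "hca_partition.csv")))
    add(write_csv_plain(out$hca$dendrogram$merges,
                        file.path(out_dir, "hca_merges.csv")))
  }
  manifest <- file.path(out_dir, "manifest.txt")
  cfg_lines <- vapply(names(config), function(k)
    sprintf("config %s: %s", k, paste(format(config[[k]]), collapse = ",")),
    character(1))
  sums <- tools::md5sum(sort(unlist(artifacts)))
  writeLines(c(cfg_lines,
               sprintf("artifact %s %s", sums, basename(names(sums)))),
             manifest)
  out$manifest <- manifest
  note("done: %d artifacts, manifest %s", length(artifacts), manifest)
  invisible(out)
}
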