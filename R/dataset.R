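# Dataset assembly: phantoms -> boundary voltages (with the cyclic noise
# schedule) -> HTV pre-reconstructions, stored as named arrays.

#' Build a complete simulation dataset
#'
#' Generates `n` phantoms, computes their boundary voltages with the
#' linearized forward model, applies the cyclic noise schedule
#' (clean / 30 / 45 / 55 dB by sample index), and optionally fills the HTV
#' pre-reconstructions used as network inputs.
#'
#' @param n number of samples.
#' @param base_seed seed; phantom `i` uses `base_seed + i - 1` and its noise
#'   draw `base_seed + 100000 + i`.
#' @param sens an [build_sensitivity()] object (built on demand if missing).
#' @param config a [tissue_config()].
#' @param htv logical: compute HTV pre-reconstructions now.
#' @param htv_config an [htv_config()].
#' @param schedule logical: apply the noise schedule (otherwise all clean).
#' @return object of class `"eit_dataset"` with arrays `truth` and `labels`
#'   `(g, g, n)`, `voltages_clean` and `voltages` `(208, n)`, `snr_tag` (n),
#'   `htv` `(g, g, n)` or `NULL`, plus the generating `sens` reference and
#'   seeds.
#' @export
eit_dataset <- function(n, base_seed = 1L, sens = NULL,
                        config = tissue_config(), htv = TRUE,
                        htv_config = legeit::htv_config(),
                        schedule = TRUE) {
  if (is.null(sens)) sens <- build_sensitivity()
  g <- sens$mesh$grid
  phs <- generate_dataset(n, base_seed, config = config, grid = g,
                          radius = sens$mesh$radius)
  truth <- array(0, c(g, g, n)); labels <- array(0L, c(g, g, n))
  vc <- matrix(0, nrow(sens$J), n)
  for (i in seq_len(n)) {
    truth[, , i] <- phs[[i]]$conductivity
    labels[, , i] <- phs[[i]]$labels
    vc[, i] <- solve_forward(sens, phs[[i]])
  }
  tag <- if (schedule) noise_schedule(seq_len(n) - 1L) else rep("clean", n)
  v <- vc
  for (i in seq_len(n)) {
    s <- snr_of_tag(tag[i])
    if (is.finite(s))
      v[, i] <- as.vector(add_noise(vc[, i], s, seed = base_seed + 100000L + i))
  }
  hv <- if (htv) prereconstruct(v, sens, htv_config) else NULL
  structure(list(truth = truth, labels = labels, voltages_clean = vc,
                 voltages = v, snr_tag = tag, htv = hv,
                 phantoms = phs, sens = sens, base_seed = base_seed,
                 htv_config = htv_config, n = n),
            class = "eit_dataset")
}

#' @export
print.eit_dataset <- function(x, ...) {
  cat("EIT dataset:", x$n, "samples,", dim(x$truth)[1], "x", dim(x$truth)[2],
      "pixels; HTV", if (is.null(x$htv)) "not computed" else "computed", "\n")
  cat("  noise tags:", paste(names(table(x$snr_tag)), table(x$snr_tag),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Save a dataset container
#'
#' Writes the named arrays (`conductivity`, `labels`, `voltages`,
#' `htv_input`, `snr_tag`) to a single R-native container file plus a JSON
#' sidecar with the generation configuration and seeds.
#'
#' @param dataset an [eit_dataset()] object.
#' @param file output path (`.rds`); the sidecar gets `.json` appended.
#' @return the file path, invisibly.
#' @export
save_dataset <- function(dataset, file) {
  arrays <- list(conductivity = dataset$truth, labels = dataset$labels,
                 voltages = dataset$voltages,
                 voltages_clean = dataset$voltages_clean,
                 htv_input = dataset$htv, snr_tag = dataset$snr_tag)
  saveRDS(arrays, file)
  side <- list(n = dataset$n, base_seed = dataset$base_seed,
               grid = dim(dataset$truth)[1],
               radius = dataset$sens$mesh$radius,
               htv_config = unclass(dataset$htv_config),
               created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' Load a dataset container saved by [save_dataset()]
#' @param file path to the `.rds` container.
#' @return list of named arrays.
#' @export
load_dataset <- function(file) readRDS(file)
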