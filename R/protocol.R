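#' 16-electrode adjacent-adjacent measurement protocol
#'
#' Current is driven through each of the 16 adjacent electrode pairs
#' `(k, k+1)` in turn; for each drive, voltages are read on every adjacent
#' pair that shares no electrode with the drive pair (13 pairs), giving
#' 16 x 13 = 208 measurements.  The canonical ordering is drive-index major,
#' measurement start-electrode minor (ascending, skipping excluded pairs).
#'
#' @param n_electrodes number of boundary electrodes (16).
#' @return object of class `"eit_protocol"`: `drive_pairs` (16 x 2),
#'   `measure_pairs` (list per drive), and `table` (208 x 4 matrix with
#'   columns drive+, drive-, meas+, meas-).
#' @export
build_protocol <- function(n_electrodes = 16L) {
  L <- as.integer(n_electrodes)
  nxt <- function(k) (k %% L) + 1L
  drive <- cbind(seq_len(L), nxt(seq_len(L)))
  measure <- vector("list", L)
  rows <- list()
  for (k in seq_len(L)) {
    keep <- list()
    for (m in seq_len(L)) {
      pair <- c(m, nxt(m))
      if (any(pair %in% drive[k, ])) next
      keep[[length(keep) + 1L]] <- pair
      rows[[length(rows) + 1L]] <- c(drive[k, ], pair)
    }
    measure[[k]] <- do.call(rbind, keep)
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("drive_a", "drive_b", "meas_a", "meas_b")
  structure(list(n_electrodes = L, drive_pairs = drive,
                 measure_pairs = measure, table = tab,
                 n_measurements = nrow(tab)),
            class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("Adjacent-adjacent EIT protocol:", x$n_electrodes, "electrodes,",
      x$n_measurements, "measurements\n")
  invisible(x)
}

#' Serialize a protocol to JSON
#' @param protocol an [build_protocol()] object.
#' @param file optional path; if missing the JSON string is returned.
#' @export
protocol_json <- function(protocol, file = NULL) {
  js <- jsonlite::toJSON(list(n_electrodes = protocol$n_electrodes,
                              table = protocol$table), dataframe = "columns")
  if (is.null(file)) js else { writeLines(js, file); invisible(file) }
}
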