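#' Write / read a decay stack as multi-page TIFF plus JSON sidecar
#'
#' One 16-bit TIFF page per time bin (counts above 65535 are an error) and a
#' JSON sidecar holding the timing metadata
#' (`laser_period_ns`, `bin_width_ns`, `n_bins`, `harmonic`, `irf_sigma_ns`,
#' `seed`, `channel`). `prefix` is the path without extension; the pair
#' `<prefix>.tif` / `<prefix>.json` is written.
#'
#' @param stack A `decay_stack`.
#' @param prefix File path prefix (no extension).
#' @param irf_sigma_ns,seed Optional metadata recorded in the sidecar.
#' @return `read_decay_stack` returns the `decay_stack`; the writer returns
#'   `prefix` invisibly.
#' @export
write_decay_stack <- function(stack, prefix, irf_sigma_ns = 0, seed = NULL) {
  stopifnot(inherits(stack, "decay_stack"))
  if (max(stack$counts) > 65535) stop("counts exceed 16-bit TIFF range")
  nt <- dim(stack$counts)[1]
  pages <- lapply(seq_len(nt), function(k) stack$counts[k, , ] / 65535)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16,
                  compression = "none", reduce = FALSE)
  meta <- list(
    format = "mobflim-decay/1",
    laser_period_ns = stack$laser_period_ns,
    bin_width_ns = diff(stack$bin_centers_ns[1:2]),
    n_bins = nt,
    harmonic = stack$harmonic,
    irf_sigma_ns = irf_sigma_ns,
    seed = seed,
    channel = stack$channel,
    package_version = as.character(utils::packageVersion("mobflim"))
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' @rdname write_decay_stack
#' @export
read_decay_stack <- function(prefix) {
  tifp <- paste0(prefix, ".tif")
  jsp <- paste0(prefix, ".json")
  if (!file.exists(jsp)) stop("missing JSON sidecar: ", jsp)
  meta <- jsonlite::read_json(jsp, simplifyVector = TRUE)
  if (!identical(meta$format, "mobflim-decay/1")) {
    stop("not a mobflim decay sidecar: ", jsp)
  }
  pages <- tryCatch(tiff::readTIFF(tifp, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable decay TIFF ", tifp,
                                             ": ", conditionMessage(e)))
  if (length(pages) != meta$n_bins) {
    stop("decay TIFF has ", length(pages), " pages but sidecar declares ",
         meta$n_bins, " bins")
  }
  nr <- nrow(pages[[1]])
  nc <- ncol(pages[[1]])
  counts <- array(0, dim = c(meta$n_bins, nr, nc))
  for (k in seq_along(pages)) counts[k, , ] <- pages[[k]]
  bc <- (seq_len(meta$n_bins) - 0.5) * meta$bin_width_ns
  decay_stack(counts, bc, meta$laser_period_ns,
              channel = meta$channel, harmonic = meta$harmonic)
}

#' Write / read a 16-bit intensity or label image
#'
#' @param img Non-negative integer-valued matrix (<= 65535).
#' @param path TIFF path.
#' @return The matrix (reader) or `path` invisibly (writer).
#' @export
write_image16 <- function(img, path) {
  if (max(img) > 65535 || min(img) < 0) stop("image out of 16-bit range")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_image16
#' @export
read_image16 <- function(path) {
  tryCatch(tiff::readTIFF(path, as.is = TRUE),
           error = function(e) stop("unreadable TIFF ", path, ": ",
                                    conditionMessage(e)))
}

#' Write / read a phasor image as a 2-page float TIFF plus JSON sidecar
#'
#' Pages hold g and s as 32-bit floats. Because the TIFF writer stores
#' float samples on a \[0, 1\] scale, coordinates are affinely encoded as
#' `(value - offset) / span` with the encoding recorded in the sidecar;
#' the default covers \[-1, 2\], ample for calibrated phasors.
#'
#' @param phasor A `phasor_image`.
#' @param prefix Path prefix (no extension).
#' @return Reader returns the `phasor_image` (without counts; `total_counts`
#'   is stored as a third page); writer returns `prefix` invisibly.
#' @export
write_phasor_image <- function(phasor, prefix) {
  stopifnot(inherits(phasor, "phasor_image"))
  off <- -1
  span <- 3
  enc <- function(m) {
    m[!is.finite(m)] <- off  # NA sentinel: encodes to 0
    pmin(pmax((m - off) / span, 0), 1)
  }
  mx <- max(phasor$total_counts, 1)
  tiff::writeTIFF(list(enc(phasor$g), enc(phasor$s), phasor$total_counts / mx),
                  paste0(prefix, ".tif"), bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  meta <- list(format = "mobflim-phasor/1", offset = off, span = span,
               counts_scale = mx, omega = phasor$omega,
               harmonic = phasor$harmonic,
               laser_period_ns = phasor$laser_period_ns,
               channel = phasor$channel,
               package_version = as.character(utils::packageVersion("mobflim")))
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' @rdname write_phasor_image
#' @export
read_phasor_image <- function(prefix) {
  jsp <- paste0(prefix, ".json")
  if (!file.exists(jsp)) stop("missing JSON sidecar: ", jsp)
  meta <- jsonlite::read_json(jsp, simplifyVector = TRUE)
  if (!identical(meta$format, "mobflim-phasor/1")) {
    stop("not a mobflim phasor sidecar: ", jsp)
  }
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  dec <- function(m) m * meta$span + meta$offset
  g <- dec(pages[[1]])
  s <- dec(pages[[2]])
  tot <- pages[[3]] * meta$counts_scale
  g[tot == 0] <- NA_real_
  s[tot == 0] <- NA_real_
  structure(list(g = g, s = s, total_counts = tot, omega = meta$omega,
                 harmonic = meta$harmonic,
                 laser_period_ns = meta$laser_period_ns,
                 channel = meta$channel), class = "phasor_image")
}

mob_csv_columns <- c("cell_id", "population", "orr", "alpha_bound",
                     "tau_bound_ns", "edge_center_ratio", "polarity",
                     "area_px", "mean_nadph", "mean_fad", "timepoint", "hoxb5")

#' Write / read a per-cell MOB table as CSV
#'
#' The header is fixed (cell_id, population, orr, alpha_bound, tau_bound_ns,
#' edge_center_ratio, polarity, area_px, mean_nadph, mean_fad, timepoint,
#' hoxb5); the reader parses by header name so column order in the file does
#' not matter, and errors on missing required columns.
#'
#' @param cells MOB table.
#' @param path CSV path.
#' @return Reader returns the table; writer returns `path` invisibly.
#' @export
write_cell_table <- function(cells, path) {
  missing_cols <- setdiff(mob_csv_columns, names(cells))
  for (cl in missing_cols) cells[[cl]] <- NA
  utils::write.csv(cells[, mob_csv_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "orr", "alpha_bound", "tau_bound_ns",
                "edge_center_ratio", "polarity")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cell CSV lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (cl in setdiff(mob_csv_columns, names(tab))) tab[[cl]] <- NA
  tab[, union(mob_csv_columns, names(tab))]
}

#' Write / read a rendered field directory
#'
#' Persists a `flim_field` as the on-disk dialect: `nadph_decay.tif/.json`,
#' `fad.tif`, `mask.tif` (16-bit cell ids, 0 = background) and `truth.csv`.
#'
#' @param field A `flim_field`.
#' @param dir Output directory (created if needed).
#' @return Reader returns a list (`nadph`, `fad`, `mask`, `truth`); writer
#'   returns `dir` invisibly.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "flim_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_decay_stack(field$nadph, file.path(dir, "nadph_decay"),
                    irf_sigma_ns = field$acq$irf_sigma_ns,
                    seed = field$acq$seed)
  write_image16(round(field$fad), file.path(dir, "fad.tif"))
  write_image16(field$mask, file.path(dir, "mask.tif"))
  utils::write.csv(field$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_field
#' @export
read_field <- function(dir) {
  list(
    nadph = read_decay_stack(file.path(dir, "nadph_decay")),
    fad = read_image16(file.path(dir, "fad.tif")),
    mask = read_image16(file.path(dir, "mask.tif")),
    truth = utils::read.csv(file.path(dir, "truth.csv"),
                            stringsAsFactors = FALSE)
  )
}
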