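#' Write a movie as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are rescaled to `[0, 1]` for 16-bit storage; the scale
#' factor is stored in a `.json` sidecar next to the TIFF so that
#' [readMovieTiff()] restores the original values (up to 16-bit
#' quantisation).
#'
#' @param movie a [Movie].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeMovieTiff <- function(movie, path) {
  stopifnot(is(movie, "Movie"))
  f <- frames(movie)
  mx <- max(f, 1e-12)
  pages <- lapply(seq_len(dim(f)[1L]), function(t)
    matrix(f[t, , ] / mx, dim(f)[2L], dim(f)[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(scale = mx, frameRateHz = frameRate(movie),
         channel = movie@channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [writeMovieTiff()]
#'
#' @param path `.tif` path with its `.json` sidecar.
#' @return a [Movie].
#' @export
readMovieTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  f <- array(0, c(length(pages), d[1L], d[2L]))
  for (t in seq_along(pages)) f[t, , ] <- pages[[t]] * meta$scale
  new("Movie", frames = f, frameRateHz = meta$frameRateHz,
      channel = meta$channel)
}

#' Write a correlation map as 32-bit float TIFF plus JSON sidecar
#'
#' Correlations in `[-1, 1]` are stored as `(v + 1) / 2`; undefined
#' pixels are written as 0 and recorded in the sidecar's mask.
#'
#' @param map a [CorrelationMap].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeCorrelationMapTiff <- function(map, path) {
  stopifnot(is(map, "CorrelationMap"))
  v <- mapValues(map)
  und <- which(is.na(v))
  v[is.na(v)] <- -1
  tiff::writeTIFF((v + 1) / 2, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(clusterId = map@clusterId, larvaId = map@larvaId,
         nEvents = map@nEvents, undefinedPixels = und),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a correlation map written by [writeCorrelationMapTiff()]
#'
#' @param path `.tif` path with its `.json` sidecar.
#' @return a [CorrelationMap].
#' @export
readCorrelationMapTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * 2 - 1
  if (length(meta$undefinedPixels)) v[meta$undefinedPixels] <- NA_real_
  new("CorrelationMap", values = v, clusterId = as.integer(meta$clusterId),
      larvaId = meta$larvaId, nEvents = as.integer(meta$nEvents))
}

#' Write a tail trace as a two-column CSV (`time_s`, `angle_deg`)
#'
#' @param trace a [TailTrace].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
writeTailTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "TailTrace"))
  write.csv(data.frame(time_s = trace@times, angle_deg = trace@angles),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a tail trace CSV (`time_s`, `angle_deg`)
#'
#' @param path `.csv` path.
#' @return a [TailTrace] with provenance `"direct"`.
#' @export
readTailTraceCsv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "angle_deg") %in% names(d)))
    .stopf("tail trace CSV needs columns time_s, angle_deg")
  dt <- median(diff(d$time_s))
  new("TailTrace", times = d$time_s, angles = d$angle_deg, rateHz = 1 / dt,
      provenance = "direct")
}

#' Read a tracked-points CSV (`frame`, `t_s`, `x0..x8`, `y0..y8`)
#'
#' @param path `.csv` path.
#' @return data.frame suitable for [tailTraceFromPoints()].
#' @export
readTailPoints <- function(path) {
  d <- read.csv(path)
  need <- c("t_s", paste0("x", 0:8), paste0("y", 0:8))
  if (!all(need %in% names(d)))
    .stopf("points CSV needs columns t_s, x0..x8, y0..y8")
  d
}
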