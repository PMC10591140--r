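# Plain-text interchange: sparse CSV for spike rasters (columns trial,
# neuron, time) and event tables (t, x, y, polarity), and JSON network
# checkpoints. Time indices are 0-based on disk; the in-memory convention is
# 1-based, stated here once and enforced by the round-trip tests.

#' Read and write spike-raster CSV files
#'
#' Rasters are stored sparsely: one row per spike with 0-based `time` and
#' 1-based `trial`/`neuron` columns, preceded by a comment line declaring
#' the dense dimensions. The round trip is bit-exact.
#'
#' @param raster binary `neurons x time x trials` array (or a matrix, taken
#'   as one trial).
#' @param path file path.
#' @return `read_raster_csv` returns a `"spike_raster"` array;
#'   `write_raster_csv` returns `path` invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  if (is.matrix(raster)) raster <- array(raster, c(dim(raster), 1))
  d <- dim(raster)
  idx <- which(raster == 1, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spike raster: neurons=%d time=%d trials=%d (time 0-based)",
                     d[1], d[2], d[3]), con)
  writeLines("trial,neuron,time", con)
  if (nrow(idx) > 0) {
    ord <- order(idx[, 3], idx[, 1], idx[, 2])
    writeLines(sprintf("%d,%d,%d", idx[ord, 3], idx[ord, 1], idx[ord, 2] - 1L),
               con)
  }
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#")) {
    stop("missing raster header comment line")
  }
  m <- regmatches(lines[1],
                  regexec("neurons=(\\d+) time=(\\d+) trials=(\\d+)", lines[1]))[[1]]
  if (length(m) != 4) stop("malformed raster dimension header")
  d <- as.integer(m[2:4])
  if (trimws(lines[2]) != "trial,neuron,time") {
    stop(sprintf("unexpected raster columns: %s (want trial,neuron,time)", lines[2]))
  }
  out <- array(0, d)
  class(out) <- "spike_raster"
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(out)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad)) stop(sprintf("malformed row at line %d: %s", bad[1] + 2L,
                                body[bad[1]]))
  vals <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 3,
                                  byrow = TRUE))
  if (any(is.na(vals))) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("malformed row at line %d: %s", bad + 2L, body[bad]))
  }
  if (any(vals[, 1] < 1 | vals[, 1] > d[3] | vals[, 2] < 1 | vals[, 2] > d[1] |
          vals[, 3] < 0 | vals[, 3] >= d[2])) {
    stop("raster entry outside the declared dimensions")
  }
  key <- paste(vals[, 1], vals[, 2], vals[, 3])
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (trial, neuron, time) row: %s",
                 key[anyDuplicated(key)]))
  }
  out[cbind(vals[, 2], vals[, 3] + 1L, vals[, 1])] <- 1
  out
}

#' Read and write event-table CSV files
#'
#' Columns `t, x, y, polarity` with the sensor size in a leading comment
#' line. Rows are sorted by `t` on read; coordinates outside the declared
#' sensor are an error.
#'
#' @param events event `data.frame` with attribute `"sensor"` (see
#'   [gen_event_stream()]).
#' @param path file path.
#' @export
write_event_csv <- function(events, path) {
  sensor <- attr(events, "sensor") %||% c(max(events$x) + 1, max(events$y) + 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# events: width=%d height=%d", sensor[1], sensor[2]), con)
  writeLines("t,x,y,polarity", con)
  if (nrow(events) > 0) {
    writeLines(sprintf("%d,%d,%d,%d", events$t, events$x, events$y,
                       events$polarity), con)
  }
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#")) {
    stop("missing event header comment line")
  }
  m <- regmatches(lines[1],
                  regexec("width=(\\d+) height=(\\d+)", lines[1]))[[1]]
  if (length(m) != 3) stop("malformed sensor header")
  sensor <- as.integer(m[2:3])
  if (trimws(lines[2]) != "t,x,y,polarity") {
    stop(sprintf("unexpected event columns: %s (want t,x,y,polarity)", lines[2]))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    out <- data.frame(t = integer(0), x = integer(0), y = integer(0),
                      polarity = integer(0))
    attr(out, "sensor") <- sensor
    return(out)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad)) stop(sprintf("malformed row at line %d: %s", bad[1] + 2L,
                                body[bad[1]]))
  vals <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 4,
                                  byrow = TRUE))
  if (any(is.na(vals))) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("malformed row at line %d: %s", bad + 2L, body[bad]))
  }
  if (any(vals[, 2] < 0 | vals[, 2] >= sensor[1] |
          vals[, 3] < 0 | vals[, 3] >= sensor[2])) {
    stop(sprintf("event coordinates outside the declared %dx%d sensor",
                 sensor[1], sensor[2]))
  }
  ord <- order(vals[, 1])
  out <- data.frame(t = vals[ord, 1], x = vals[ord, 2], y = vals[ord, 3],
                    polarity = vals[ord, 4])
  attr(out, "sensor") <- sensor
  out
}

#' Save and load a network checkpoint
#'
#' Portable JSON checkpoint: all layer and head parameters at full floating
#' precision plus the noise configuration, neuron constants and a free-form
#' metadata list (seeds, provenance). The round trip reproduces the network
#' exactly.
#'
#' @param net an [nsnn_network()].
#' @param path file path (`.json`).
#' @param metadata optional named list stored alongside the parameters.
#' @export
save_network <- function(net, path, metadata = list()) {
  stopifnot(inherits(net, "nsnn"))
  obj <- list(
    format = "nsnn-checkpoint-1",
    n_in = net$n_in, sizes = net$sizes,
    neuron = net$layers[[1]]$params[c("tau", "v_th", "u_reset")],
    layers = lapply(net$layers, function(ly) {
      list(W = ly$W, b = ly$b,
           noise = list(family = ly$noise$family, scale = ly$noise$scale))
    }),
    head = if (net$head$type == "softmax") {
      list(type = "softmax", n_class = net$head$n_class,
           W = net$head$W, b = net$head$b)
    } else list(type = "custom"),
    metadata = metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "nsnn-checkpoint-1")) {
    stop("not an nsnn checkpoint file")
  }
  if (!identical(obj$head$type, "softmax")) {
    stop("only softmax-head checkpoints can be loaded standalone; ",
         "custom heads are functions and are not serialized")
  }
  params <- neuron_params(obj$neuron$tau, obj$neuron$v_th, obj$neuron$u_reset)
  sizes <- as.integer(unlist(obj$sizes))
  L <- length(sizes)
  noise <- lapply(obj$layers, function(ly) {
    noise_model(ly$noise$family,
                if (ly$noise$family == "none") 0.3 else ly$noise$scale)
  })
  net <- nsnn_network(unlist(obj$n_in), sizes,
                      head = head_softmax(unlist(obj$head$n_class)),
                      noise = noise, params = params, seed = 0)
  to_mat <- function(W, nr) matrix(unlist(W), nrow = nr, byrow = TRUE)
  for (l in seq_len(L)) {
    net$layers[[l]]$W <- to_mat(obj$layers[[l]]$W, sizes[l])
    net$layers[[l]]$b <- as.numeric(unlist(obj$layers[[l]]$b))
  }
  net$head$W <- to_mat(obj$head$W, net$head$n_class)
  net$head$b <- as.numeric(unlist(obj$head$b))
  net
}
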