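## Delimited-text I/O. Instrument exports in this domain are plain text, so
## matrices are stored as: '#'-prefixed metadata header lines (axis kind and
## units are mandatory), then a header row with the spectral axis, then one
## row per delay with the delay in the first column.

.num <- function(x) trimws(formatC(x, digits = 15, format = "g"))

.metaLines <- function(meta) {
  keep <- !vapply(meta, function(v) is.null(v) || all(is.na(v)), logical(1))
  paste0("# ", names(meta)[keep], ": ",
         vapply(meta[keep], function(v) paste(v, collapse = " "), character(1)))
}

.parseMeta <- function(lines) {
  m <- sub("^#\\s*", "", lines)
  kv <- regmatches(m, regexpr(":", m), invert = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2) out[[trimws(p[1])]] <- trimws(p[2])
  out
}

#' Write a time-resolved matrix as delimited text
#'
#' Tab-separated, with metadata (axis kind, units, excitation, seed) as
#' \code{#} header lines; first row = spectral axis, first column = delay.
#' Round-trips losslessly through \code{\link{readMatrix}} to within float
#' text precision (1e-12 relative).
#'
#' @param x a \linkS4class{SpectralMatrix} or \linkS4class{RamanTimeSeries}
#' @param path output file
#' @param extraMeta named list of extra metadata lines (e.g. seed,
#'   config_hash) for provenance
#' @return \code{path}, invisibly
#' @export
writeMatrix <- function(x, path, extraMeta = list()) {
  ai <- .axisInfo(x)
  meta <- c(list(format = "ultrafastSpec matrix v1",
                 axis = if (ai$unit == "nm") "wavelength" else "raman_shift",
                 axis_unit = ai$unit, delay_unit = "ps",
                 signal_unit = if (ai$unit == "nm") "mOD" else "percent_gain"),
            if (is(x, "SpectralMatrix")) list(
              excitation_nm = if (is.na(x@excitation)) NULL else x@excitation,
              label = if (nzchar(x@label)) x@label else NULL)
            else list(
              pump_nm = if (is.na(x@pumpNm)) NULL else x@pumpNm,
              side = x@side),
            extraMeta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.metaLines(meta), con)
  writeLines(paste(c("delay", .num(ai$axis)), collapse = "\t"), con)
  body <- cbind(.num(ai$times),
                matrix(.num(ai$values), nrow = length(ai$times)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a time-resolved matrix written by \code{\link{writeMatrix}}
#'
#' @param path input file
#' @return a \linkS4class{SpectralMatrix} (wavelength axis) or
#'   \linkS4class{RamanTimeSeries} (Raman shift axis), per the header
#' @export
readMatrix <- function(path) {
  lines <- readLines(path)
  isMeta <- grepl("^#", lines)
  meta <- .parseMeta(lines[isMeta])
  if (is.null(meta$axis) || is.null(meta$axis_unit) ||
      is.null(meta$delay_unit))
    stop("missing units header: axis, axis_unit and delay_unit are required")
  body <- lines[!isMeta & nzchar(lines)]
  if (length(body) < 2) stop("no data rows")
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1) stop("ragged rows in ", path)
  axis <- as.numeric(cells[[1]][-1])
  rows <- do.call(rbind, lapply(cells[-1], function(r) as.numeric(r)))
  if (anyNA(rows) || anyNA(axis)) stop("non-numeric cells in ", path)
  times <- rows[, 1]
  if (identical(meta$delay_unit, "fs")) times <- times / 1000
  else if (!identical(meta$delay_unit, "ps"))
    stop("unsupported delay unit: ", meta$delay_unit)
  vals <- rows[, -1, drop = FALSE]
  if (identical(meta$axis, "wavelength")) {
    spectralMatrix(times, axis, vals,
                   excitation = if (!is.null(meta$excitation_nm))
                     as.numeric(meta$excitation_nm) else NA_real_,
                   label = if (!is.null(meta$label)) meta$label else "")
  } else if (identical(meta$axis, "raman_shift")) {
    ramanTimeSeries(times, axis, vals,
                    pumpNm = if (!is.null(meta$pump_nm))
                      as.numeric(meta$pump_nm) else NA_real_,
                    side = if (!is.null(meta$side)) meta$side else "anti_stokes")
  } else stop("unknown axis kind: ", meta$axis)
}

#' Two-column trace and spectrum I/O
#'
#' Traces are written as (delay ps, signal); 1D spectra as
#' (wavelength nm, intensity); metadata as \code{#} header lines.
#'
#' @param x a \linkS4class{TimeTrace} or \linkS4class{Spectrum1D}
#' @param path file path
#' @return \code{path} (writers, invisibly) or the object (readers)
#' @export
writeTrace <- function(x, path) {
  stopifnot(is(x, "TimeTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.metaLines(list(format = "ultrafastSpec trace v1",
                             delay_unit = "ps",
                             window = if (all(is.na(x@window))) NULL
                                      else paste(.num(x@window), collapse = " "),
                             window_unit = if (nzchar(x@windowUnit))
                               x@windowUnit else NULL,
                             label = if (nzchar(x@label)) x@label else NULL)),
             con)
  writeLines(paste(.num(x@times), .num(x@intensity), sep = "\t"), con)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  isMeta <- grepl("^#", lines)
  meta <- .parseMeta(lines[isMeta])
  cells <- strsplit(lines[!isMeta & nzchar(lines)], "\t", fixed = TRUE)
  if (length(unique(lengths(cells))) != 1 || lengths(cells)[1] != 2)
    stop("trace files must have exactly two tab-separated columns")
  m <- do.call(rbind, lapply(cells, as.numeric))
  win <- if (!is.null(meta$window))
    as.numeric(strsplit(meta$window, "\\s+")[[1]]) else c(NA_real_, NA_real_)
  timeTrace(m[, 1], m[, 2], window = win,
            windowUnit = if (!is.null(meta$window_unit)) meta$window_unit else "",
            label = if (!is.null(meta$label)) meta$label else "")
}

#' @rdname writeTrace
#' @param spectrum a \linkS4class{Spectrum1D}
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum1D"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.metaLines(list(format = "ultrafastSpec spectrum v1",
                             axis_unit = "nm", axis_kind = spectrum@axisKind,
                             label = if (nzchar(spectrum@label))
                               spectrum@label else NULL)), con)
  writeLines(paste(.num(spectrum@axis), .num(spectrum@intensity), sep = "\t"),
             con)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readSpectrum <- function(path) {
  lines <- readLines(path)
  isMeta <- grepl("^#", lines)
  meta <- .parseMeta(lines[isMeta])
  cells <- strsplit(lines[!isMeta & nzchar(lines)], "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(cells, as.numeric))
  spectrum1D(m[, 1], m[, 2],
             axisKind = if (!is.null(meta$axis_kind)) meta$axis_kind
                        else "absorption",
             label = if (!is.null(meta$label)) meta$label else "")
}

## ---------------------------------------------------------------------------
## Kinetic-scheme serialization (plain-text config block; lossless)

#' Serialize a kinetic scheme to a plain config list
#'
#' The list (species, edges with rates, initial populations) round-trips
#' losslessly through \code{schemeFromConfig} and can be embedded in a YAML
#' pipeline configuration.
#'
#' @param scheme a \linkS4class{KineticScheme}
#' @return a list with elements species, edges, initial
#' @export
schemeToConfig <- function(scheme) {
  K <- scheme@rateMatrix
  sp <- scheme@species
  edges <- data.frame(from = character(0), to = character(0),
                      rate = numeric(0))
  for (j in seq_along(sp)) for (i in seq_along(sp))
    if (i != j && K[i, j] > 0)
      edges <- rbind(edges, data.frame(from = sp[j], to = sp[i],
                                       rate = K[i, j]))
  for (j in seq_along(sp)) if (scheme@sinkRates[j] > 0)
    edges <- rbind(edges, data.frame(from = sp[j], to = "ground",
                                     rate = scheme@sinkRates[j]))
  list(species = sp,
       edges = lapply(seq_len(nrow(edges)), function(r)
         list(from = edges$from[r], to = edges$to[r], rate = edges$rate[r])),
       initial = as.list(setNames(scheme@initial, sp)))
}

#' @rdname schemeToConfig
#' @param config a list as produced by \code{schemeToConfig}
#' @export
schemeFromConfig <- function(config) {
  edges <- do.call(rbind, lapply(config$edges, function(e)
    data.frame(from = e$from, to = e$to, rate = e$rate)))
  init <- unlist(config$initial)
  sch <- buildTarget(edges, initial = init[init > 0])
  ## restore the declared species order
  ord <- match(config$species, sch@species)
  if (anyNA(ord)) stop("config species missing from the edge list")
  new("KineticScheme", species = sch@species[ord],
      rateMatrix = sch@rateMatrix[ord, ord, drop = FALSE],
      initial = sch@initial[ord], sinkRates = sch@sinkRates[ord])
}
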