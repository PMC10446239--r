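## Polytope and sample exchange formats.
##
## A polytope directory holds dense numeric CSV tables plus meta.json:
##   raw/preprocessed: A_eq.csv, b_eq.csv, A_in.csv, b_in.csv, flux_names.txt
##   reduced:          A.csv, b.csv, K.csv, nu0.csv, flux_names.txt
##   rounded:          additionally R.csv, R_inv.csv, shift.csv and the parent
##                     reduced tables (transform bundle kept with the samples
##                     so stored rounded states stay interpretable)
## A sample directory holds chain_<i>.csv (rows = samples, columns = named
## fluxes), optional chain_<i>_rounded.csv, meta.json (config, seeds, timings)
## and optionally samples.rds as a lossless binary container.

.writeMat <- function(x, path) {
  utils::write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

.readMat <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "numeric"))
}

.readVec <- function(path) as.numeric(.readMat(path))

#' Write a polytope exchange directory
#'
#' @param poly a \linkS4class{FluxPolytope}, \linkS4class{ReducedPolytope} or
#'   \linkS4class{RoundedPolytope}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writePolytope <- function(poly, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(kind = class(poly)[1L], package = "chrrt")
  if (is(poly, "FluxPolytope")) {
    .writeMat(poly@Aeq, file.path(dir, "A_eq.csv"))
    .writeMat(matrix(poly@beq, ncol = 1), file.path(dir, "b_eq.csv"))
    .writeMat(poly@Ain, file.path(dir, "A_in.csv"))
    .writeMat(matrix(poly@bin, ncol = 1), file.path(dir, "b_in.csv"))
    writeLines(poly@fluxNames, file.path(dir, "flux_names.txt"))
    meta$units <- poly@units
    if (is(poly, "PreprocessedPolytope")) {
      pv <- poly@provenance
      meta$provenance <- list(
        removedRows = pv$removedRows,
        tightened = if (!is.null(pv$tightened)) pv$tightened else NULL,
        log = pv$log)
    }
  } else if (is(poly, "ReducedPolytope")) {
    .writeMat(poly@A, file.path(dir, "A.csv"))
    .writeMat(matrix(poly@b, ncol = 1), file.path(dir, "b.csv"))
    .writeMat(poly@K, file.path(dir, "K.csv"))
    .writeMat(matrix(poly@nu0, ncol = 1), file.path(dir, "nu0.csv"))
    writeLines(poly@fluxNames, file.path(dir, "flux_names.txt"))
  } else if (is(poly, "RoundedPolytope")) {
    .writeMat(poly@A, file.path(dir, "A_rounded.csv"))
    .writeMat(matrix(poly@b, ncol = 1), file.path(dir, "b_rounded.csv"))
    tr <- poly@transform
    .writeMat(tr@R, file.path(dir, "R.csv"))
    .writeMat(tr@Rinv, file.path(dir, "R_inv.csv"))
    .writeMat(matrix(tr@shift, ncol = 1), file.path(dir, "shift.csv"))
    p <- poly@parent
    .writeMat(p@A, file.path(dir, "A.csv"))
    .writeMat(matrix(p@b, ncol = 1), file.path(dir, "b.csv"))
    .writeMat(p@K, file.path(dir, "K.csv"))
    .writeMat(matrix(p@nu0, ncol = 1), file.path(dir, "nu0.csv"))
    writeLines(p@fluxNames, file.path(dir, "flux_names.txt"))
  } else stop("unsupported polytope class: ", class(poly)[1L], call. = FALSE)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a polytope exchange directory
#'
#' @param dir directory written by \code{\link{writePolytope}} (or assembled by
#'   hand with the same table layout).
#' @return the polytope object of the kind recorded in \code{meta.json}.
#' @export
readPolytope <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath))
    stop("not a polytope directory (missing meta.json): ", dir, call. = FALSE)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  fn <- readLines(file.path(dir, "flux_names.txt"))
  kind <- meta$kind
  if (kind %in% c("FluxPolytope", "PreprocessedPolytope")) {
    poly <- fluxPolytope(
      Ain = .readMat(file.path(dir, "A_in.csv")),
      bin = .readVec(file.path(dir, "b_in.csv")),
      Aeq = {
        Aeq <- .readMat(file.path(dir, "A_eq.csv"))
        if (nrow(Aeq) == 0L || (nrow(Aeq) == 1L && all(!nzchar(readLines(file.path(dir, "A_eq.csv"), n = 1L))))) NULL else Aeq
      },
      beq = .readVec(file.path(dir, "b_eq.csv")),
      fluxNames = fn, units = meta$units %||% "mmol/gDW/h")
    return(poly)
  }
  if (kind == "ReducedPolytope") {
    return(new("ReducedPolytope",
               A = .readMat(file.path(dir, "A.csv")),
               b = .readVec(file.path(dir, "b.csv")),
               K = .readMat(file.path(dir, "K.csv")),
               nu0 = .readVec(file.path(dir, "nu0.csv")),
               fluxNames = fn))
  }
  if (kind == "RoundedPolytope") {
    parent <- new("ReducedPolytope",
                  A = .readMat(file.path(dir, "A.csv")),
                  b = .readVec(file.path(dir, "b.csv")),
                  K = .readMat(file.path(dir, "K.csv")),
                  nu0 = .readVec(file.path(dir, "nu0.csv")),
                  fluxNames = fn)
    tr <- new("RoundingTransform",
              R = .readMat(file.path(dir, "R.csv")),
              Rinv = .readMat(file.path(dir, "R_inv.csv")),
              shift = .readVec(file.path(dir, "shift.csv")),
              provenance = list(source = "file"))
    return(new("RoundedPolytope",
               A = .readMat(file.path(dir, "A_rounded.csv")),
               b = .readVec(file.path(dir, "b_rounded.csv")),
               transform = tr, parent = parent))
  }
  stop("unknown polytope kind in meta.json: ", kind, call. = FALSE)
}

#' Write a sample set
#'
#' One CSV table per chain (rows = stored samples, columns = named fluxes),
#' a JSON metadata sidecar (configuration, seed, thinning constant, timings)
#' and, with \code{format = "rds"}, an additional lossless binary container.
#'
#' @param samples a \linkS4class{FluxSampleSet}.
#' @param dir output directory.
#' @param format \code{"csv"} (portable) or \code{"rds"} (adds a bit-exact
#'   binary container next to the CSVs).
#' @return \code{dir}, invisibly.
#' @export
writeSamples <- function(samples, dir, format = c("csv", "rds")) {
  format <- match.arg(format)
  stopifnot(is(samples, "FluxSampleSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- samples@config
  for (i in seq_along(samples@samplesOriginal)) {
    ch <- samples@samplesOriginal[[i]]
    utils::write.csv(as.data.frame(ch), file.path(dir, sprintf("chain_%d.csv", i)),
                     row.names = FALSE)
    if (length(samples@samplesRounded) >= i && !is.null(samples@samplesRounded[[i]])) {
      .writeMat(samples@samplesRounded[[i]],
                file.path(dir, sprintf("chain_%d_rounded.csv", i)))
    }
  }
  meta <- list(
    nChains = length(samples@samplesOriginal),
    N = cfg$N, tau = cfg$tau, seed = cfg$seed,
    burninFrac = cfg$burninFrac, zeroTol = cfg$zeroTol,
    storeRounded = isTRUE(cfg$storeRounded),
    fluxNames = fluxNames(samples),
    timings = samples@timings)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (format == "rds")
    saveRDS(samples, file.path(dir, "samples.rds"))
  invisible(dir)
}

#' Read a sample set
#'
#' Reads the binary container if present (bit-exact), otherwise reconstructs
#' the set from the CSV tables and metadata sidecar.
#'
#' @param dir directory written by \code{\link{writeSamples}}.
#' @return a \linkS4class{FluxSampleSet}.
#' @export
readSamples <- function(dir) {
  rds <- file.path(dir, "samples.rds")
  if (file.exists(rds)) return(readRDS(rds))
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath))
    stop("not a sample directory (missing meta.json): ", dir, call. = FALSE)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$nChains) || is.null(meta$N))
    stop("corrupt sample metadata in ", metaPath, call. = FALSE)
  chains <- vector("list", meta$nChains)
  roundedChains <- list()
  for (i in seq_len(meta$nChains)) {
    f <- file.path(dir, sprintf("chain_%d.csv", i))
    if (!file.exists(f)) stop("missing chain table: ", f, call. = FALSE)
    chains[[i]] <- as.matrix(utils::read.csv(f, check.names = FALSE))
    fr <- file.path(dir, sprintf("chain_%d_rounded.csv", i))
    if (file.exists(fr)) roundedChains[[i]] <- .readMat(fr)
  }
  cfg <- if (meta$nChains > 0L) {
    unclass(samplerConfig(N = meta$N, tau = meta$tau,
                          nChains = meta$nChains, seed = meta$seed,
                          zeroTol = meta$zeroTol %||% 1e-12,
                          burninFrac = meta$burninFrac %||% 0,
                          storeRounded = isTRUE(meta$storeRounded)))
  } else list(nChains = 0L)
  new("FluxSampleSet", samplesOriginal = chains,
      samplesRounded = roundedChains,
      config = cfg,
      timings = as.data.frame(meta$timings))
}
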