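#' Ground-truth manifests
#'
#' Every synthetic generator returns, next to its pixel or trajectory data, a
#' `gt_manifest` that records the exact ground truth (per-track labels, true
#' beat frequencies, positive-area fraction, analytic crescent lengths, ...)
#' so that every downstream metric can be validated without re-reading pixels.
#' Manifests serialize to JSON and round-trip losslessly.
#'
#' @param kind generator kind: `"cilia"`, `"beads"`, `"marker"` or
#'   `"crescents"`.
#' @param ... named ground-truth fields (scalars, vectors, data frames, or
#'   matrices).
#' @return A list of class `gt_manifest`.
#' @export
gt_manifest <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "gt_manifest")
}

#' @export
print.gt_manifest <- function(x, ...) {
  cat(sprintf("<gt_manifest: %s> fields: %s\n", x$kind,
              paste(setdiff(names(x), "kind"), collapse = ", ")))
  invisible(x)
}

#' Write / read a ground-truth manifest as JSON
#'
#' Matrices are stored row-major with explicit dimensions; data frames as
#' column records. `read_manifest(write_manifest(m, p))` reproduces `m`.
#'
#' @param manifest a [gt_manifest].
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the restored [gt_manifest].
#' @export
write_manifest <- function(manifest, path) {
  enc <- lapply(manifest, function(v) {
    if (is.matrix(v)) list(.matrix = TRUE, dim = dim(v), data = as.vector(v))
    else if (is.data.frame(v)) list(.df = TRUE, data = as.list(v))
    else v
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- lapply(raw, function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) {
      m <- matrix(unlist(v$data), v$dim[1], v$dim[2])
      storage.mode(m) <- if (all(m == round(m))) "integer" else "double"
      m
    } else if (is.list(v) && isTRUE(v$.df)) {
      as.data.frame(v$data)
    } else v
  })
  structure(dec, class = "gt_manifest")
}
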