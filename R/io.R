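#' Serialize a mode set to CSV
#'
#' Writes the coefficient matrix with full double precision plus a header of
#' basis parameters, so optimized modes re-load bit-exactly.
#'
#' @param modes A [mode_set()].
#' @param path Output file.
#' @export
write_modes_csv <- function(modes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mospade modes: dim=%d M=%d sigma=%.17g J=%d label=%s",
                     modes$cbasis$dim, modes$cbasis$M, modes$cbasis$sigma,
                     modes$J, if (is.null(modes$label)) "" else modes$label), con)
  utils::write.table(format(modes$V, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Read a mode set written by [write_modes_csv()]
#' @param path CSV file.
#' @return A `mospade_modes`.
#' @export
read_modes_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  f <- function(key) sub(sprintf(".*%s=([^ ]*).*", key), "\\1", hdr)
  dim <- as.integer(f("dim")); M <- as.integer(f("M")); sigma <- as.numeric(f("sigma"))
  lab <- f("label"); if (lab == "") lab <- NULL
  V <- as.matrix(utils::read.table(path, sep = ",", skip = 1))
  dimnames(V) <- NULL
  mode_set(V, computation_basis(psf_model(sigma, dim), M), label = lab)
}

#' Write a matrix as an ASCII PGM grayscale image
#'
#' Plain-text P2 format, for quick visual inspection of 2D scenes and
#' reconstructions; values are linearly mapped to 0..255.
#'
#' @param m Numeric matrix (rows = x, columns = y).
#' @param path Output file.
#' @export
write_pgm <- function(m, path) {
  r <- range(m)
  g <- if (diff(r) == 0) matrix(0L, nrow(m), ncol(m))
       else matrix(as.integer(round(255 * (m - r[1]) / diff(r))), nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(g), nrow(g)), "255"), con)
  utils::write.table(g, con, sep = " ", row.names = FALSE, col.names = FALSE)
}

#' Build scene and measurement settings from a YAML config
#'
#' Reads a key/value configuration describing the PSF (`psf.sigma`,
#' `psf.dim`), the scene (`scene.name` or `basis.kind` with `basis.a`,
#' `basis.extent`, `scene.contrast`, `scene.background`, ...) and optional
#' `optimizer.*` settings, and instantiates the corresponding objects.
#'
#' @param path YAML file.
#' @return List with `psf`, `source`, `optimizer`, and the raw `config`.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  psf <- psf_model(sigma = cfg$psf$sigma %||% 1, dim = cfg$psf$dim %||% 1)
  sc <- cfg$scene %||% list()
  b <- cfg$basis %||% list()
  kind <- b$kind %||% "rect-1d"
  source <- if (kind == "delta-comb") {
    point_comb(sc$n_points %||% 5, sc$dx %||% 0.3)
  } else if (kind == "rect-1d") {
    extended_source(sc$name %||% "bump", a = b$a %||% 0.8,
                    extent = b$extent %||% 12)
  } else if (kind == "rect-2d") {
    scene_2d(sc$name %||% "siemens", grid_n = b$grid_n %||% 24,
             bin_width = b$a %||% 0.9, contrast = sc$contrast %||% 0.025,
             background = sc$background %||% 1)
  } else stop("unknown basis.kind: ", kind)
  opt <- do.call(optimizer_config, cfg$optimizer %||% list())
  list(psf = psf, source = source, optimizer = opt, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
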