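# OpenDX scalar-field I/O for potential grids (the exchange format of
# APBS/VMD-style grid maps).  Data stream is z-fastest, per the format.

#' Write a potential grid as an OpenDX scalar field
#'
#' @param grid a `potential_grid`.
#' @param path output path (conventionally `.dx`).
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# smfsbd potential grid, kind %s", grid$kind),
    sprintf("object 1 class gridpositions counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$spacing),
    sprintf("delta 0 %.6g 0", grid$spacing),
    sprintf("delta 0 0 %.6g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  n3 <- (length(v) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(v)) {
    writeLines(paste(sprintf("%.9g", v[(n3 + 1):length(v)]),
                     collapse = " "), con)
  }
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field as a potential grid
#'
#' Supports regular grids with axis-aligned, equal deltas, as written by
#' [write_dx()] (and by APBS-style tools).
#'
#' @param path path to a `.dx` file.
#' @param kind grid kind to stamp on the result; inferred from the
#'   header comment when absent.
#' @return a `potential_grid`.
#' @export
read_dx <- function(path, kind = NULL) {
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp)),
                                "\\s+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("origin", "",
    grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l) {
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- unique(diag(dmat)[diag(dmat) > 0])
  if (length(spacing) != 1L || any(dmat[upper.tri(dmat)] != 0) ||
      any(dmat[lower.tri(dmat)] != 0)) {
    stop("only axis-aligned grids with uniform spacing are supported")
  }
  i0 <- grep("data follows", lines)[1]
  tail_at <- grep("^attribute|^object \"", lines)
  i1 <- min(tail_at[tail_at > i0], length(lines) + 1L) - 1L
  v <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):i1]), "\\s+")))
  stopifnot(length(v) == prod(counts))
  vals <- aperm(array(v, rev(counts)), c(3, 2, 1))
  if (is.null(kind)) {
    km <- regmatches(lines[1], regexpr("kind \\S+", lines[1]))
    kind <- if (length(km)) sub("kind ", "", km) else "electrostatic"
  }
  potential_grid(org, spacing, vals, kind)
}

#' Build the full grid set for a receptor
#'
#' Electrostatic plus the three category LJ grids, each smoothed by the
#' 1 Angstrom Gaussian filter, on a common frame.
#'
#' @param receptor an `atom_set`.
#' @param body_categories category parameter frame of the mobile body
#'   (from [assign_lj_categories()]); defaults to categories computed
#'   from the receptor itself.
#' @param ionic_strength_mM,temperature_K,spacing,margin_A,cap_kJ_mol
#'   passed through to [electrostatic_grid()] / [lj_grid()].
#' @param smooth_width_A Gaussian filter width; 0 disables smoothing.
#' @return list of class `grid_set` with elements `electrostatic`,
#'   `LJ_H`, `LJ_ON`, `LJ_CS` (absent categories omitted).
#' @export
build_grid_set <- function(receptor, body_categories = NULL,
                           ionic_strength_mM = 250, temperature_K = 300,
                           spacing = 1, margin_A = 30, cap_kJ_mol = 100,
                           smooth_width_A = 1.0) {
  if (is.null(body_categories)) {
    body_categories <- assign_lj_categories(receptor)$category_params
  }
  out <- list(electrostatic = smooth_grid(
    electrostatic_grid(receptor, ionic_strength_mM, temperature_K,
                       spacing, margin_A), smooth_width_A))
  for (cc in body_categories$category) {
    out[[paste0("LJ_", cc)]] <- smooth_grid(
      lj_grid(receptor, body_categories, cc, spacing, cap_kJ_mol,
              margin_A), smooth_width_A)
  }
  class(out) <- "grid_set"
  out
}
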