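#' Otoferlin annotation map
#'
#' An annotation map holds the interval layers over the 1979-residue long
#' isoform of otoferlin that the ConStruct predictors are computed from:
#' the seven C2 domains, the four intrinsically disordered regions (IDRs),
#' composition-biased (low-complexity) stretches, the coiled coil, and a
#' 46-interval exon partition mapping each residue to the OTOF coding exon
#' it falls in.
#'
#' Intervals are 1-based and closed on both ends. Within one layer,
#' intervals must be pairwise non-overlapping; the exon layer must
#' additionally cover every residue exactly once.
#'
#' @param config path to an annotation config JSON with fields
#'   `protein_length` and layers `domains`, `regions`, `comp_bias`,
#'   `coiled_coil`, `exons`, each a list of `{start, end, code, name}`
#'   records. Defaults to the packaged otoferlin config, whose domain and
#'   region coordinates are the literature-reported values; the packaged
#'   composition-bias, coiled-coil and exon-partition layers are synthetic
#'   placeholders (flagged in the config's `synthetic_layers` field) and
#'   should be replaced for any analysis that depends on them.
#' @return an object of class `otof_annotation`: a list with
#'   `protein_length` and one data frame (`start`, `end`, `code`, `name`)
#'   per layer.
#' @examples
#' map <- otoferlin_annotation()
#' map$domains
#' domain_of(1504, map)
#' @export
otoferlin_annotation <- function(config = system.file("extdata",
                                                      "otoferlin_annotation.json",
                                                      package = "ConStructOTOF")) {
  if (!file.exists(config)) stop("annotation config not found: ", config)
  raw <- jsonlite::fromJSON(config)
  if (is.null(raw$protein_length)) stop("config lacks 'protein_length'")
  L <- as.integer(raw$protein_length)
  layer <- function(name, allow_empty = TRUE) {
    x <- raw[[name]]
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
      if (!allow_empty) stop("config layer '", name, "' is missing or empty")
      return(data.frame(start = integer(0), end = integer(0),
                        code = integer(0), name = character(0)))
    }
    x <- as.data.frame(x)
    validate_layer(x, name, L)
  }
  map <- structure(list(
    protein_length = L,
    domains     = layer("domains"),
    regions     = layer("regions"),
    comp_bias   = layer("comp_bias"),
    coiled_coil = layer("coiled_coil"),
    exons       = layer("exons", allow_empty = FALSE)
  ), class = "otof_annotation")

  if (anyDuplicated(map$domains$code)) stop("duplicate domain codes")
  if (anyDuplicated(map$regions$code)) stop("duplicate region codes")
  covered <- rep(0L, L)
  for (i in seq_len(nrow(map$exons)))
    covered[map$exons$start[i]:map$exons$end[i]] <-
      covered[map$exons$start[i]:map$exons$end[i]] + 1L
  if (any(covered != 1L))
    stop("exon layer must partition residues 1..", L, " exactly once")
  map
}

# shared layer validation: types, bounds, within-layer non-overlap
validate_layer <- function(x, name, L) {
  need <- c("start", "end", "code")
  if (!all(need %in% names(x)))
    stop("layer '", name, "' needs columns start, end, code")
  if (is.null(x$name)) x$name <- rep(NA_character_, nrow(x))
  x <- data.frame(start = as.integer(x$start), end = as.integer(x$end),
                  code = as.integer(x$code), name = as.character(x$name))
  if (any(is.na(x$start)) || any(is.na(x$end)) || any(is.na(x$code)))
    stop("layer '", name, "': non-integer start/end/code")
  if (any(x$start < 1L) || any(x$end > L) || any(x$start > x$end))
    stop("layer '", name, "': intervals must satisfy 1 <= start <= end <= ", L)
  o <- order(x$start)
  xs <- x[o, , drop = FALSE]
  if (nrow(xs) > 1L && any(xs$start[-1L] <= xs$end[-nrow(xs)]))
    stop("layer '", name, "': overlapping intervals")
  xs
}

check_positions <- function(position, map) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) ||
      any(position > map$protein_length))
    stop("position out of range 1..", map$protein_length)
  position
}

# layers are stored sorted by start, so findInterval locates the candidate
interval_code <- function(position, layer) {
  if (nrow(layer) == 0L) return(rep(0L, length(position)))
  i <- findInterval(position, layer$start)
  hit <- i >= 1L & position <= layer$end[pmax(i, 1L)]
  out <- rep(0L, length(position))
  out[hit] <- layer$code[i[hit]]
  out
}

#' Predictor lookups against an annotation map
#'
#' `domain_of()` returns the C2-domain code (1-7) containing a residue
#' position, or 0 outside all domains. `region_of()` does the same for the
#' four IDR regions (codes 1-4). `comp_bias_flag()` and `coiled_coil_flag()`
#' return 1 if the position lies in any composition-biased or coiled-coil
#' interval and 0 otherwise. `exon_of()` returns the exon number (1-46 for
#' the default partition) of the unique exon interval containing the
#' position.
#'
#' All functions are vectorised over `position` and error on positions
#' outside `1..protein_length`.
#'
#' @param position integer vector of residue positions (1-based)
#' @param map an [otoferlin_annotation()] map
#' @return integer vector, one value per position
#' @examples
#' map <- otoferlin_annotation()
#' domain_of(c(50, 99, 1504), map)   # 1, 0, 6
#' region_of(150, map)               # 1
#' @export
domain_of <- function(position, map) {
  interval_code(check_positions(position, map), map$domains)
}

#' @rdname domain_of
#' @export
region_of <- function(position, map) {
  interval_code(check_positions(position, map), map$regions)
}

#' @rdname domain_of
#' @export
comp_bias_flag <- function(position, map) {
  as.integer(interval_code(check_positions(position, map), map$comp_bias) > 0L)
}

#' @rdname domain_of
#' @export
coiled_coil_flag <- function(position, map) {
  as.integer(interval_code(check_positions(position, map), map$coiled_coil) > 0L)
}

#' @rdname domain_of
#' @export
exon_of <- function(position, map) {
  code <- interval_code(check_positions(position, map), map$exons)
  if (any(code == 0L)) stop("position not covered by the exon map")
  code
}

#' @export
print.otof_annotation <- function(x, ...) {
  cat("Otoferlin annotation map (", x$protein_length, " residues)\n", sep = "")
  for (nm in c("domains", "regions", "comp_bias", "coiled_coil", "exons"))
    cat(sprintf("  %-12s %d interval(s)\n", nm, nrow(x[[nm]])))
  invisible(x)
}
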