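FEATURE_NAMES <- c("position", "exon_number", "blosum_score", "domain_code",
                   "region_code", "comp_bias", "coiled_coil",
                   "phylop100", "phylop30")

#' Encode variants as ConStruct predictor vectors
#'
#' Computes the nine ConStruct predictors for each variant: residue
#' position, exon number, BLOSUM80 substitution score, C2-domain code
#' (0-7), IDR region code (0-4), composition-bias and coiled-coil flags,
#' and the two phyloP conservation values (100-vertebrate and 30-primate
#' tracks). Conservation is a property of the underlying nucleotide change
#' and must come with the records; missing phyloP values are an error, not
#' silently imputed. The exon number is taken from the record when present
#' and otherwise looked up in the annotation map.
#'
#' @param records variant data frame with at least `position`, `ref_aa`,
#'   `alt_aa`, `phylop100`, `phylop30` (see [read_variant_table()])
#' @param map an [otoferlin_annotation()] map
#' @param matrix a substitution matrix, default [blosum80()]
#' @return data frame with the nine predictor columns, one row per record
#' @examples
#' map <- otoferlin_annotation()
#' v <- data.frame(position = 1504, ref_aa = "L", alt_aa = "P",
#'                 phylop100 = 7.5, phylop30 = 0.6)
#' encode_features(v, map)
#' @export
encode_features <- function(records, map = otoferlin_annotation(),
                            matrix = blosum80()) {
  records <- as.data.frame(records)
  need <- c("position", "ref_aa", "alt_aa", "phylop100", "phylop30")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (anyNA(records$phylop100) || anyNA(records$phylop30))
    stop("missing phyloP conservation value(s); conservation must be ",
         "supplied with the records, it is not imputed")
  pos <- check_positions(records$position, map)
  exon <- exon_of(pos, map)
  if ("exon_number" %in% names(records)) {
    given <- suppressWarnings(as.integer(records$exon_number))
    exon[!is.na(given)] <- given[!is.na(given)]
  }
  data.frame(
    position     = pos,
    exon_number  = exon,
    blosum_score = blosum_score(records$ref_aa, records$alt_aa, matrix),
    domain_code  = domain_of(pos, map),
    region_code  = region_of(pos, map),
    comp_bias    = comp_bias_flag(pos, map),
    coiled_coil  = coiled_coil_flag(pos, map),
    phylop100    = as.numeric(records$phylop100),
    phylop30     = as.numeric(records$phylop30)
  )
}

#' @describeIn encode_features encode one variant given as scalars;
#'   returns a one-row data frame.
#' @param position,ref_aa,alt_aa,phylop100,phylop30,exon_number scalar
#'   variant fields
#' @export
encode_variant <- function(position, ref_aa, alt_aa, phylop100, phylop30,
                           exon_number = NA_integer_,
                           map = otoferlin_annotation(),
                           matrix = blosum80()) {
  encode_features(data.frame(position = position, ref_aa = ref_aa,
                             alt_aa = alt_aa, phylop100 = phylop100,
                             phylop30 = phylop30, exon_number = exon_number),
                  map, matrix)
}
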