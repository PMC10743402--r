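# three-letter <-> one-letter residue codes (20 standard amino acids)
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

VARIANT_COLUMNS <- c("position", "ref_aa", "alt_aa", "label", "rs_id",
                     "allele_frequency", "phylop100", "phylop30",
                     "exon_number")

#' Parse protein variant notation
#'
#' Parses strings like `"Leu1504Pro"` (three-letter reference residue,
#' 1-based protein position, three-letter alternate residue) into one-letter
#' codes. Case-insensitive in the residue codes; vectorised.
#'
#' @param text character vector of variant notations
#' @return data frame with columns `position`, `ref_aa`, `alt_aa`
#' @examples
#' parse_protein_variant(c("Leu1504Pro", "Val456Met"))
#' @export
parse_protein_variant <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", text))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed variant notation: ", paste(text[bad], collapse = ", "))
  norm <- function(s) {  # Leu / LEU / leu -> Leu
    s <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, 3)))
    code <- AA_THREE_TO_ONE[s]
    if (anyNA(code))
      stop("unknown residue code(s): ",
           paste(unique(s[is.na(code)]), collapse = ", "))
    unname(code)
  }
  data.frame(position = as.integer(vapply(m, `[`, "", 3L)),
             ref_aa = norm(vapply(m, `[`, "", 2L)),
             alt_aa = norm(vapply(m, `[`, "", 4L)))
}

#' Format one-letter variant triple as three-letter notation
#' @param position,ref_aa,alt_aa variant key vectors
#' @return character vector like `"Leu1504Pro"`
#' @export
format_protein_variant <- function(position, ref_aa, alt_aa) {
  one2three <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)
  paste0(one2three[ref_aa], position, one2three[alt_aa])
}

#' Read and write SAV (single amino-acid variant) tables
#'
#' Variant tables are tab-separated with a header. The variant itself is
#' given either as a `variant` column in three-letter notation
#' (`Leu1504Pro`) or as explicit `position`, `ref_aa`, `alt_aa` columns.
#' Optional columns: `label` (one of `pathogenic`, `benign`, `vus`),
#' `rs_id`, `allele_frequency`, `phylop100`, `phylop30`, `exon_number`.
#' Missing values are written and read as `"-"` (the convention of curated
#' hearing-loss variant tables); `write_variant_table()` followed by
#' `read_variant_table()` is the identity on the defined columns.
#'
#' Duplicate variants (same position/ref/alt) are an error, as are rows
#' that fail to parse (reported with their line numbers).
#'
#' @param path file path
#' @param records data frame of variants as returned by
#'   `read_variant_table()` or the simulators
#' @param na_string missing-value token, default `"-"`
#' @return `read_variant_table()`: a data frame with the columns above;
#'   `write_variant_table()`: the path, invisibly
#' @export
read_variant_table <- function(path, na_string = "-") {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         na.strings = c(na_string, "", "NA"))
  if (nrow(x) == 0L) {
    out <- data.frame(position = integer(0), ref_aa = character(0),
                      alt_aa = character(0))
    for (col in setdiff(VARIANT_COLUMNS, names(out))) out[[col]] <- logical(0)
    return(out)
  }
  if ("variant" %in% names(x)) {
    key <- tryCatch(parse_protein_variant(x$variant), error = function(e) e)
    if (inherits(key, "error")) {
      ok <- grepl("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", x$variant)
      stop("unparseable variant notation at line(s) ",
           paste(which(!ok) + 1L, collapse = ", "), ": ", conditionMessage(key))
    }
  } else if (all(c("position", "ref_aa", "alt_aa") %in% names(x))) {
    key <- data.frame(position = as.integer(x$position),
                      ref_aa = toupper(x$ref_aa), alt_aa = toupper(x$alt_aa))
  } else {
    stop("variant table needs a 'variant' column or position/ref_aa/alt_aa")
  }
  bad <- which(is.na(key$position) | key$position < 1L |
                 is.na(key$ref_aa) | is.na(key$alt_aa) |
                 key$ref_aa == key$alt_aa)
  if (length(bad))
    stop("invalid variant row(s) at line(s) ", paste(bad + 1L, collapse = ", "))
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate variant row(s) at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  out <- key
  out$label <- if ("label" %in% names(x)) {
    lab <- tolower(x$label)
    ok <- is.na(lab) | lab %in% c("pathogenic", "benign", "vus")
    if (!all(ok)) stop("invalid label at line(s) ",
                       paste(which(!ok) + 1L, collapse = ", "))
    lab
  } else NA_character_
  out$rs_id <- if ("rs_id" %in% names(x)) x$rs_id else NA_character_
  num <- function(col) if (col %in% names(x)) as.numeric(x[[col]]) else NA_real_
  out$allele_frequency <- num("allele_frequency")
  out$phylop100 <- num("phylop100")
  out$phylop30 <- num("phylop30")
  out$exon_number <- if ("exon_number" %in% names(x))
    as.integer(x$exon_number) else NA_integer_
  if (any(!is.na(out$allele_frequency) &
          (out$allele_frequency < 0 | out$allele_frequency > 1)))
    stop("allele_frequency outside [0, 1]")
  out
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(records, path, na_string = "-") {
  records <- as.data.frame(records)
  stopifnot(all(c("position", "ref_aa", "alt_aa") %in% names(records)))
  cols <- intersect(VARIANT_COLUMNS, names(records))
  utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = na_string)
  invisible(path)
}

#' Read per-method prediction score tables
#'
#' Reads a tab-separated table of per-variant method scores in the layout
#' of dbNSFP-style extracts: variant key columns (either `variant` notation
#' or `position`/`ref_aa`/`alt_aa`) plus, per method `m`, any subset of
#' `m_score`, `m_rankscore`, `m_call` columns. Calls use `P` (pathogenic) /
#' `B` (benign); when a method has no call column its calls are derived
#' from its scores and the configured cutoff and direction. A missing score
#' with no call stays missing (absence of evidence is not a benign call).
#'
#' @param path file path
#' @param methods list of method configs, each a list with `name`, and for
#'   call derivation `cutoff` and `direction` (one of
#'   `"higher_is_pathogenic"`, `"lower_is_pathogenic"`)
#' @param na_string missing-value token
#' @return a data frame (class `method_score_table`) with the variant key
#'   and per-method `*_score`, `*_rankscore`, `*_call` columns; the method
#'   configs are kept in `attr(, "methods")`
#' @export
read_method_scores <- function(path, methods, na_string = "-") {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         na.strings = c(na_string, "", "NA"))
  key <- if ("variant" %in% names(x)) parse_protein_variant(x$variant)
  else data.frame(position = as.integer(x$position),
                  ref_aa = toupper(x$ref_aa), alt_aa = toupper(x$alt_aa))
  out <- key
  for (m in methods) {
    nm <- m$name
    sc <- paste0(nm, "_score"); rk <- paste0(nm, "_rankscore")
    cl <- paste0(nm, "_call")
    if (!any(c(sc, rk, cl) %in% names(x)))
      stop("method '", nm, "' has no columns in ", path)
    out[[sc]] <- if (sc %in% names(x)) as.numeric(x[[sc]]) else NA_real_
    out[[rk]] <- if (rk %in% names(x)) as.numeric(x[[rk]]) else NA_real_
    if (any(!is.na(out[[rk]]) & (out[[rk]] <= 0 | out[[rk]] > 1)))
      stop("rank scores for '", nm, "' outside (0, 1]")
    if (cl %in% names(x)) {
      calls <- toupper(x[[cl]])
      if (any(!is.na(calls) & !calls %in% c("P", "B")))
        stop("call column for '", nm, "' has values outside {P, B, missing}")
      out[[cl]] <- calls
    } else {
      out[[cl]] <- derive_calls(out[[sc]], m)
    }
  }
  structure(out, methods = methods,
            class = c("method_score_table", class(out)))
}

derive_calls <- function(score, method) {
  if (is.null(method$cutoff) || is.null(method$direction))
    stop("method '", method$name,
         "' needs cutoff and direction to derive calls")
  dir <- match.arg(method$direction,
                   c("higher_is_pathogenic", "lower_is_pathogenic"))
  path <- if (dir == "higher_is_pathogenic") score >= method$cutoff
  else score <= method$cutoff
  ifelse(is.na(score), NA_character_, ifelse(path, "P", "B"))
}
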