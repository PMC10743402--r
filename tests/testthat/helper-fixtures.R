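# shared fixtures, all built in code

# write a config JSON and load it as an annotation map
toy_annotation <- function(L = 20,
                           exons = data.frame(start = c(1, 11), end = c(10, 20),
                                              code = 1:2),
                           domains = data.frame(start = 3, end = 7, code = 1),
                           regions = data.frame(start = integer(0),
                                                end = integer(0),
                                                code = integer(0)),
                           comp_bias = data.frame(start = integer(0),
                                                  end = integer(0),
                                                  code = integer(0)),
                           coiled_coil = data.frame(start = integer(0),
                                                    end = integer(0),
                                                    code = integer(0))) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(protein_length = L, domains = domains,
                            regions = regions, comp_bias = comp_bias,
                            coiled_coil = coiled_coil, exons = exons),
                       path, auto_unbox = TRUE, digits = NA)
  otoferlin_annotation(path)
}

default_map <- otoferlin_annotation()
default_matrix <- blosum80()

# linearly separable toy set: pathogenic iff phylop100 > 5
separable_records <- function(n = 100, seed = 42) {
  set.seed(seed)
  pos <- sample(default_map$protein_length, n)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ref <- sample(aa, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(aa, r), 1), "")
  lab <- rep(c("pathogenic", "benign"), length.out = n)
  data.frame(position = pos, ref_aa = ref, alt_aa = unname(alt), label = lab,
             phylop100 = ifelse(lab == "pathogenic", runif(n, 6, 9),
                                runif(n, 0, 4)),
             phylop30 = rnorm(n, 0.3, 0.2))
}

# random variant table with missing optional fields, for round-trip checks
random_variant_table <- function(n = 25, seed = 7) {
  set.seed(seed)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ref <- sample(aa, n, replace = TRUE)
  data.frame(position = sample(1979, n),
             ref_aa = ref,
             alt_aa = vapply(ref, function(r) sample(setdiff(aa, r), 1), ""),
             label = sample(c("pathogenic", "benign", "vus"), n, TRUE),
             rs_id = ifelse(runif(n) < 0.3, NA,
                            paste0("rs", sample(1e6, n))),
             allele_frequency = ifelse(runif(n) < 0.5, NA,
                                       round(runif(n, 0, 1e-3), 7)),
             phylop100 = round(rnorm(n, 2, 3), 3),
             phylop30 = round(rnorm(n, 0, 0.5), 3),
             exon_number = sample(46, n, TRUE))
}

table2_path <- system.file("extdata", "otof_prioritized_vus.tsv",
                           package = "ConStructOTOF")
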