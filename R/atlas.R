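# Desikan-Killiany cortical parcellation: 34 gyral regions per hemisphere.
# Base abbreviations follow the conventional short names used in the
# cortical-thickness covariance literature; odd indices are left-hemisphere.
dk_regions <- data.frame(
  base = c("BSTS", "CAC", "CMF", "CUN", "ENT", "FUSI", "IP", "IT", "ISTC",
           "LOCC", "LOF", "LING", "MOF", "MT", "PHG", "PARC", "POPE", "PORB",
           "PTRI", "PERI", "PSTC", "PC", "PREC", "PCUN", "RAC", "RMF", "SF",
           "SP", "ST", "SMAR", "FP", "TP", "TT", "INS"),
  name = c("Bank of the superior temporal sulcus", "Caudal anterior cingulate",
           "Caudal middle frontal", "Cuneus", "Entorhinal", "Fusiform gyrus",
           "Inferior parietal", "Inferior temporal", "Isthmus of the cingulate",
           "Lateral occipital", "Lateral orbitofrontal", "Lingual gyrus",
           "Medial orbitofrontal", "Middle temporal", "Parahippocampal",
           "Paracentral lobule", "Pars opercularis (Inferior frontal)",
           "Pars orbitalis (Inferior frontal)",
           "Pars triangularis (Inferior frontal)", "Pericalcarine",
           "Postcentral gyrus", "Posterior cingulate", "Precentral gyrus",
           "Precuneus", "Rostral anterior cingulate", "Rostral middle frontal",
           "Superior frontal", "Superior parietal", "Superior temporal",
           "Supramarginal", "Frontal pole", "Temporal pole",
           "Transverse temporal", "Insula"),
  stringsAsFactors = FALSE
)

#' Built-in Desikan-Killiany cortical atlas (68 regions)
#'
#' The 68-region gyral parcellation used to define network nodes: 34
#' anatomical regions per hemisphere, indexed 1..68 with odd indices in the
#' left hemisphere and even indices in the right. Node order throughout the
#' package (matrices, partitions, cohort columns) is this index order.
#'
#' @return a data.frame with columns `index`, `abbreviation` (base name
#'   suffixed `.L`/`.R`, e.g. `"POPE.L"`), `name`, `hemisphere` (`"L"`/`"R"`).
#' @examples
#' atlas <- dk_atlas()
#' atlas[atlas$abbreviation == "PCUN.R", ]
#' @export
dk_atlas <- function() {
  n <- nrow(dk_regions)
  data.frame(
    index = seq_len(2L * n),
    abbreviation = paste0(rep(dk_regions$base, each = 2L), c(".L", ".R")),
    name = rep(dk_regions$name, each = 2L),
    hemisphere = rep(c("L", "R"), n),
    stringsAsFactors = FALSE
  )
}

#' Write the built-in atlas to CSV
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_atlas <- function(path) {
  utils::write.csv(dk_atlas(), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
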