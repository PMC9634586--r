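# Default per-drug metadata. The three conversion anchors published for this
# class of analysis (clonazepam 20 DME/mg, zolpidem 0.5 DME/mg, lorazepam
# 10 DME/mg, diazepam identity) are fixed; the remaining equivalences follow a
# published 10-mg-diazepam-reference equivalence table and the DDDs the WHO
# ATC/DDD index, both overridable by config.
.default_drug_table <- function() {
  d <- data.frame(
    drug_id = c("alprazolam", "estazolam", "lorazepam", "oxazepam",
                "midazolam", "diazepam", "clonazepam", "nitrazepam",
                "zolpidem", "zopiclone", "eszopiclone", "zaleplon"),
    atc_code = c("N05BA12", "N05CD04", "N05BA06", "N05BA04",
                 "N05CD08", "N05BA01", "N03AE01", "N05CD02",
                 "N05CF02", "N05CF01", "N05CF04", "N05CF03"),
    drug_class = c(rep("BZD", 8L), rep("Z_DRUG", 4L)),
    dme_per_mg = c(20, 5, 10, 0.5, 4/3, 1, 20, 1, 0.5, 2/3, 10/3, 0.5),
    ddd_mg = c(1, 3, 2.5, 50, 15, 10, 8, 5, 10, 7.5, 3, 10),
    stringsAsFactors = FALSE
  )
  rownames(d) <- d$drug_id
  d
}

# Illustrative approved-indication map: ICD-10 code prefixes per drug.
# Clonazepam is deliberately epilepsy-only; hypnotic Z-drugs map to sleep
# disorders; anxiolytic benzodiazepines to neurotic/anxiety blocks.
.default_indications <- function() {
  list(
    alprazolam  = c("F40", "F41"),
    estazolam   = c("G47", "F51"),
    lorazepam   = c("F40", "F41", "G47"),
    oxazepam    = c("F40", "F41", "G47"),
    midazolam   = c("G47"),
    diazepam    = c("F40", "F41", "G40", "G41"),
    clonazepam  = c("G40", "G41"),
    nitrazepam  = c("G47", "G40"),
    zolpidem    = c("G47", "F51"),
    zopiclone   = c("G47", "F51"),
    eszopiclone = c("G47", "F51"),
    zaleplon    = c("G47", "F51")
  )
}

.icd10_prefix_re <- "^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{0,4})?$"

.validate_drug_row <- function(id, row) {
  if (!is.finite(row$dme_per_mg) || row$dme_per_mg <= 0)
    stop(sprintf("drug '%s': dme_per_mg must be a positive number (got %s)",
                 id, format(row$dme_per_mg)), call. = FALSE)
  if (!is.finite(row$ddd_mg) || row$ddd_mg <= 0)
    stop(sprintf("drug '%s': ddd_mg must be a positive number (got %s)",
                 id, format(row$ddd_mg)), call. = FALSE)
  if (!row$drug_class %in% c("BZD", "Z_DRUG"))
    stop(sprintf("drug '%s': drug_class must be 'BZD' or 'Z_DRUG' (got '%s')",
                 id, row$drug_class), call. = FALSE)
  invisible(TRUE)
}

#' Load the drug registry (DME conversions, DDDs, approved indications)
#'
#' The registry holds per-drug metadata for the twelve benzodiazepine
#' receptor agonists covered by the analysis: drug class (benzodiazepine or
#' Z-drug), the conversion factor to diazepam milligram equivalents (DME per
#' mg of drug), the WHO defined daily dose (DDD, mg), and the set of ICD-10
#' code prefixes regarded as approved indications for the drug.
#'
#' Without a config path the packaged default registry is returned. A YAML
#' config with top-level sections \code{drugs:} and/or \code{indications:}
#' merges over the defaults: per-drug fields override field-by-field, new
#' drugs are added, and indication lists replace the default list for that
#' drug. Entries violating the registry invariants (non-positive conversion
#' or DDD, unknown class, malformed ICD-10 prefix) are rejected with an error
#' naming the offending entry.
#'
#' @param config_path optional path to a YAML registry config.
#' @return an object of class \code{dme_registry}: a list with elements
#'   \code{drugs} (data frame with columns drug_id, atc_code, drug_class,
#'   dme_per_mg, ddd_mg), \code{indications} (named list of ICD-10 prefixes),
#'   and \code{provenance} (character).
#' @examples
#' reg <- load_registry()
#' to_dme(reg, "clonazepam", 0.5)
#' @export
load_registry <- function(config_path = NULL) {
  drugs <- .default_drug_table()
  indications <- .default_indications()
  provenance <- paste(
    "Anchored conversions (clonazepam 20, zolpidem 0.5, lorazepam 10,",
    "diazepam 1 DME/mg); other equivalences from a published",
    "10-mg-diazepam-reference table; DDDs from the WHO ATC/DDD index.")

  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop("registry config not found: ", config_path, call. = FALSE)
    cfg <- yaml::read_yaml(config_path)
    known_fields <- c("atc_code", "drug_class", "dme_per_mg", "ddd_mg")
    for (id in names(cfg$drugs)) {
      entry <- cfg$drugs[[id]]
      bad <- setdiff(names(entry), known_fields)
      if (length(bad))
        stop(sprintf("drug '%s': unknown field(s) %s", id,
                     paste(sQuote(bad), collapse = ", ")), call. = FALSE)
      id_lc <- tolower(id)
      if (!id_lc %in% rownames(drugs)) {
        need <- setdiff(c("drug_class", "dme_per_mg", "ddd_mg"), names(entry))
        if (length(need))
          stop(sprintf("new drug '%s' needs field(s): %s", id,
                       paste(need, collapse = ", ")), call. = FALSE)
        drugs[id_lc, ] <- list(id_lc, entry$atc_code %||% NA_character_,
                               entry$drug_class, as.numeric(entry$dme_per_mg),
                               as.numeric(entry$ddd_mg))
      } else {
        for (f in intersect(names(entry), known_fields))
          drugs[id_lc, f] <- if (f %in% c("dme_per_mg", "ddd_mg"))
            as.numeric(entry[[f]]) else as.character(entry[[f]])
      }
      .validate_drug_row(id_lc, drugs[id_lc, ])
    }
    for (id in names(cfg$indications)) {
      id_lc <- tolower(id)
      if (!id_lc %in% rownames(drugs))
        stop(sprintf("indications given for unknown drug '%s'", id),
             call. = FALSE)
      codes <- as.character(unlist(cfg$indications[[id]]))
      bad <- codes[!grepl(.icd10_prefix_re, codes)]
      if (length(bad))
        stop(sprintf("drug '%s': malformed ICD-10 prefix(es) %s", id,
                     paste(sQuote(bad), collapse = ", ")), call. = FALSE)
      indications[[id_lc]] <- codes
    }
    if (!is.null(cfg$provenance)) provenance <- as.character(cfg$provenance)
  }

  for (id in rownames(drugs)) .validate_drug_row(id, drugs[id, ])
  stopifnot(all(names(indications) %in% drugs$drug_id))
  structure(list(drugs = drugs, indications = indications,
                 provenance = provenance),
            class = "dme_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dme_registry <- function(x, ...) {
  cat("DME drug registry:", nrow(x$drugs), "drugs (",
      sum(x$drugs$drug_class == "BZD"), "BZDs,",
      sum(x$drugs$drug_class == "Z_DRUG"), "Z-drugs )\n")
  print(x$drugs, row.names = FALSE)
  cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Serialise a registry to YAML config
#'
#' Writes the registry in the same format `load_registry()` reads, so that
#' save-and-reload round-trips exactly.
#'
#' @param registry a \code{dme_registry}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "dme_registry"))
  drugs <- lapply(seq_len(nrow(registry$drugs)), function(i) {
    r <- registry$drugs[i, ]
    list(atc_code = r$atc_code, drug_class = r$drug_class,
         dme_per_mg = r$dme_per_mg, ddd_mg = r$ddd_mg)
  })
  names(drugs) <- registry$drugs$drug_id
  yaml::write_yaml(list(provenance = registry$provenance, drugs = drugs,
                        indications = registry$indications), path,
                   precision = 17L)
  invisible(path)
}

.lookup_drug <- function(registry, drug_id) {
  i <- match(drug_id, registry$drugs$drug_id)
  if (anyNA(i))
    stop("unknown drug(s): ",
         paste(unique(drug_id[is.na(i)]), collapse = ", "),
         "; known drugs: ", paste(registry$drugs$drug_id, collapse = ", "),
         call. = FALSE)
  i
}

#' Convert a drug dose to diazepam milligram equivalents
#'
#' @param registry a \code{dme_registry}.
#' @param drug_id drug name(s), lowercase, present in the registry.
#' @param dose_mg nonnegative dose(s) in mg (recycled against drug_id).
#' @return dose in DME (mg diazepam equivalent); linear in dose.
#' @examples
#' reg <- load_registry()
#' to_dme(reg, "zolpidem", 20)   # 10
#' @export
to_dme <- function(registry, drug_id, dose_mg) {
  stopifnot(inherits(registry, "dme_registry"), all(dose_mg >= 0))
  i <- .lookup_drug(registry, drug_id)
  unname(dose_mg * registry$drugs$dme_per_mg[i])
}

#' Convert a total drug amount to WHO defined daily doses
#'
#' @param registry a \code{dme_registry}.
#' @param drug_id drug name(s) present in the registry.
#' @param total_mg nonnegative total amount(s) in mg.
#' @return the amount expressed in DDDs (total_mg / ddd_mg).
#' @export
to_ddd <- function(registry, drug_id, total_mg) {
  stopifnot(inherits(registry, "dme_registry"), all(total_mg >= 0))
  i <- .lookup_drug(registry, drug_id)
  unname(total_mg / registry$drugs$ddd_mg[i])
}
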