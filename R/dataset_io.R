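#' Canonical observation-table columns
#'
#' One row of the observation table is one unique control-versus-plastic
#' experimental comparison: group means, standard deviations and replicate
#' counts for one microbial (or soil) parameter, plus the moderators
#' describing the plastic treatment and experimental context.
#'
#' @return Character vector of canonical column names.
#' @export
observation_columns <- function() {
  c("study_id", "parameter_name", "parameter_group",
    "mean_control", "mean_treatment", "sd_control", "sd_treatment",
    "n_control", "n_treatment",
    "plastic_type", "general_type",
    "amount_g_per_kg", "amount_class",
    "size_um", "size_class",
    "incubation_days", "time_class",
    "ecosystem", "microbial_group")
}

.mandatory_columns <- c("study_id", "parameter_name",
                        "mean_control", "mean_treatment",
                        "n_control", "n_treatment")

#' Validate an observation table
#'
#' Checks row-level invariants: replicate counts are integers >= 1 and
#' standard deviations, when present, are non-negative. Missing standard
#' deviations are legal (they are imputed downstream) and are never treated
#' as zero.
#'
#' @param obs Data frame with (at least) the mandatory observation columns.
#' @return Data frame with columns `row`, `field`, `problem`; zero rows when
#'   the table is valid.
#' @export
validate_observations <- function(obs) {
  problems <- list()
  note <- function(rows, field, problem) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<-
        data.frame(row = rows, field = field, problem = problem)
    }
  }
  for (fld in c("n_control", "n_treatment")) {
    n <- obs[[fld]]
    bad <- which(is.na(n) | n < 1 | n != round(n))
    note(bad, fld, "replicate count must be an integer >= 1")
  }
  for (fld in c("sd_control", "sd_treatment")) {
    s <- obs[[fld]]
    if (!is.null(s)) note(which(!is.na(s) & s < 0), fld, "negative SD")
  }
  for (fld in c("mean_control", "mean_treatment")) {
    note(which(is.na(obs[[fld]])), fld, "missing mean")
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(row = integer(), field = character(), problem = character())
}

#' Read an observation table
#'
#' Reads a comma- or tab-separated observation table (header required,
#' decimal point, UTF-8), optionally renames columns through `schema`, and
#' validates row-level invariants. Rows violating an invariant abort the
#' read with an error naming the offending rows; blank SD cells are kept as
#' `NA`, never coerced to zero.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(mean_control = "Ctrl.Mean")`. Needed when reading tables with a
#'   foreign header dialect (such as a deposited dataset).
#' @param sep Field separator; guessed from the header line when `NULL`.
#' @return Validated observation data frame using canonical column names.
#' @export
read_observations <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  obs <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(obs))
    if (length(missing_src)) {
      stop("schema refers to absent columns: ",
           paste(missing_src, collapse = ", "))
    }
    idx <- match(unname(schema), names(obs))
    names(obs)[idx] <- names(schema)
  }
  absent <- setdiff(.mandatory_columns, names(obs))
  if (length(absent)) {
    stop("mandatory columns missing: ", paste(absent, collapse = ", "))
  }
  for (fld in c("sd_control", "sd_treatment")) {
    if (is.null(obs[[fld]])) obs[[fld]] <- NA_real_
  }
  probs <- validate_observations(obs)
  if (nrow(probs)) {
    stop("invalid observation rows: ",
         paste(sprintf("row %d (%s: %s)", probs$row, probs$field,
                       probs$problem), collapse = "; "))
  }
  obs
}

#' Write an observation (or effect-size) table as TSV
#'
#' @param obs Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# material classes; HDPE/LDPE are polyethylenes
.aliphatic_types  <- c("PE", "PP", "HDPE", "LDPE")
.other_types      <- c("PET", "PS", "PVC")
.degradable_types <- c("PLA", "PCL")

#' Classify continuous moderators into the standard categories
#'
#' Fills `amount_class`, `time_class`, `size_class` and `general_type` from
#' the continuous moderators and the plastic-type code:
#' * amount: low below 10 g/kg, high at or above 10 g/kg (the boundary value
#'   itself is assigned high);
#' * incubation time: short up to and including 7 days, long beyond;
#' * particle size: nano below 1 um; micro from 1 um to 5 mm inclusive;
#'   meso above 5 mm up to 25 mm; macro above 25 mm;
#' * material: aliphatic polyolefins (PE, PP and their HD/LD variants),
#'   degradable polyesters (PLA, PCL), everything else "others".
#'
#' Missing continuous moderators yield missing classes. The function is
#' idempotent. Unknown plastic-type codes are classed "others" with a
#' warning (never silently).
#'
#' @param obs Observation data frame.
#' @param collapse_degradable If `TRUE`, degradable types are folded into
#'   "others", reproducing the strict two-class material grouping.
#' @return `obs` with the class columns filled.
#' @export
classify_moderators <- function(obs, collapse_degradable = FALSE) {
  amt <- obs[["amount_g_per_kg"]]
  if (!is.null(amt)) {
    obs$amount_class <- ifelse(is.na(amt), NA_character_,
                               ifelse(amt < 10, "low", "high"))
  }
  days <- obs[["incubation_days"]]
  if (!is.null(days)) {
    obs$time_class <- ifelse(is.na(days), NA_character_,
                             ifelse(days <= 7, "short", "long"))
  }
  sz <- obs[["size_um"]]
  if (!is.null(sz)) {
    obs$size_class <- ifelse(is.na(sz), NA_character_,
                      ifelse(sz < 1, "nano",
                      ifelse(sz <= 5000, "micro",
                      ifelse(sz <= 25000, "meso", "macro"))))
  }
  type <- toupper(trimws(as.character(obs[["plastic_type"]] %||%
                                        rep(NA_character_, nrow(obs)))))
  known <- c(.aliphatic_types, .other_types, .degradable_types)
  unknown <- setdiff(unique(type[!is.na(type)]), known)
  if (length(unknown)) {
    warning("unknown plastic type code(s) classed as 'others': ",
            paste(unknown, collapse = ", "))
  }
  gen <- ifelse(is.na(type), NA_character_,
         ifelse(type %in% .aliphatic_types, "aliphatic",
         ifelse(type %in% .degradable_types, "degradable", "others")))
  if (collapse_degradable) gen[gen == "degradable"] <- "others"
  obs$general_type <- gen
  obs
}

#' Merge richness metrics into one variable
#'
#' Chao1, ACE and OTU counts all estimate taxon richness; they are relabelled
#' to the single parameter name `"richness"` so they pool together. All other
#' parameter names are untouched and the number of records never changes.
#'
#' @param obs Observation data frame.
#' @param richness_aliases Parameter names to merge.
#' @return `obs` with `parameter_name` rewritten.
#' @export
merge_richness <- function(obs,
                           richness_aliases = c("chao1", "ace", "otu_count")) {
  if (!nrow(obs)) return(obs)
  hit <- tolower(obs$parameter_name) %in% tolower(richness_aliases)
  obs$parameter_name[hit] <- "richness"
  obs
}
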