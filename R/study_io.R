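# Study-level data model: controlled vocabularies, CSV I/O, validation,
# sample-size classification and shared-control aggregation.

#' Controlled vocabularies for the study table
#'
#' Closed label sets used by [validate_study_table()]: tumour sites,
#' ethnicities, study designs and genetic-model labels.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
tumour_sites <- c(
  "bladder", "breast", "colorectum", "endometrium", "liver", "lung",
  "lymphoma", "ovaries", "pancreas", "pleura", "prostate", "stomach",
  "testicles", "thyroid", "head-and-neck", "UADT"
)

#' @rdname vocabularies
#' @export
ethnicities <- c("Caucasian", "Asian", "Mixed")

#' @rdname vocabularies
#' @export
study_designs <- c("population", "hospital", "gwas")

#' @rdname vocabularies
#' @export
genetic_models <- c("recessive", "dominant", "per-paper")

genotype_columns <- c(
  "cases_wtwt", "cases_wtmt", "cases_mtmt",
  "controls_wtwt", "controls_wtmt", "controls_mtmt"
)

study_table_columns <- c(
  "snp_id", "author", "year", "tumour_site", "country", "ethnicity",
  "design", "n_cases", "n_controls", genotype_columns,
  "reported_or", "reported_lcl", "reported_ucl", "reported_model",
  "shared_control_group"
)

#' Path to the packaged CYP1A2 study-table fixture
#'
#' Transcription of the published study-level table: one row per
#' study/SNP/tumour-site stratum with the printed crude odds ratio and 95%
#' confidence interval under the genetic model assigned to each SNP
#' (recessive for rs762551, rs2470890 and rs2472304; dominant for rs2069514,
#' rs2069526 and rs35694136). The table prints no genotype counts, so the
#' genotype-count columns are empty; the three Gulyaeva 2008 strata that
#' reuse one control series carry a common `shared_control_group` key.
#'
#' @return Path to the CSV file.
#' @export
#' @examples
#' studies <- read_study_table(snpmeta_fixture())
#' table(studies$snp_id)
snpmeta_fixture <- function() {
  system.file("extdata", "table1_fixture.csv", package = "snpmeta",
              mustWork = TRUE)
}

#' Read a study-level table
#'
#' Reads the documented CSV schema (see [snpmeta_fixture()] for a worked
#' instance) and validates every row. Each row must carry either the six
#' genotype counts or a complete reported OR / 95% CI triple.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default) any invalid row is an error; if `FALSE`
#'   invalid rows are dropped with a message and the valid rows returned.
#' @return A `study_table` (data.frame) preserving file order.
#' @export
read_study_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("study table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), study_table_columns)) {
    stop("malformed header: expected columns ",
         paste(study_table_columns, collapse = ", "))
  }
  num_cols <- c("year", "n_cases", "n_controls", genotype_columns,
                "reported_or", "reported_lcl", "reported_ucl")
  for (cl in num_cols) {
    raw[[cl]][!nzchar(raw[[cl]])] <- NA
    raw[[cl]] <- as.numeric(raw[[cl]])
  }
  raw$shared_control_group[is.na(raw$shared_control_group)] <- ""
  raw$reported_model[is.na(raw$reported_model)] <- ""
  problems <- validate_study_table(raw)
  if (nrow(problems) > 0L) {
    msg <- paste0("row ", problems$row, " [", problems$field, "]: ",
                  problems$message, collapse = "\n")
    if (strict) stop("invalid study table:\n", msg)
    message("dropping ", length(unique(problems$row)),
            " invalid row(s):\n", msg)
    raw <- raw[-unique(problems$row), , drop = FALSE]
    rownames(raw) <- NULL
  }
  class(raw) <- c("study_table", "data.frame")
  raw
}

#' Validate a study table against the schema invariants
#'
#' @param records A data.frame with the study-table columns.
#' @return A data.frame with columns `row`, `field`, `message`; zero rows
#'   when the table is valid.
#' @export
validate_study_table <- function(records) {
  bad <- list()
  flag <- function(row, field, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      row = row, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$tumour_site %in% tumour_sites)
      flag(i, "tumour_site", paste0("unknown tumour site '", r$tumour_site, "'"))
    if (!r$ethnicity %in% ethnicities)
      flag(i, "ethnicity", paste0("unknown ethnicity '", r$ethnicity, "'"))
    if (!r$design %in% study_designs)
      flag(i, "design", paste0("unknown design '", r$design, "'"))
    if (is.na(r$n_cases) || r$n_cases < 1)
      flag(i, "n_cases", "n_cases must be a positive integer")
    if (is.na(r$n_controls) || r$n_controls < 1)
      flag(i, "n_controls", "n_controls must be a positive integer")
    counts <- unlist(r[genotype_columns])
    has_counts <- all(!is.na(counts))
    has_or <- !is.na(r$reported_or) && !is.na(r$reported_lcl) &&
      !is.na(r$reported_ucl)
    if (!has_counts && !has_or)
      flag(i, "effect", "row has neither genotype counts nor a reported OR/CI")
    if (has_counts) {
      if (any(counts < 0))
        flag(i, "genotype_counts", "negative genotype count")
      if (!is.na(r$n_cases) && sum(counts[1:3]) != r$n_cases)
        flag(i, "genotype_counts", "case genotype counts do not sum to n_cases")
      if (!is.na(r$n_controls) && sum(counts[4:6]) != r$n_controls)
        flag(i, "genotype_counts",
             "control genotype counts do not sum to n_controls")
    }
    if (has_or) {
      if (!(r$reported_lcl > 0 && r$reported_lcl < r$reported_ucl))
        flag(i, "reported_ci", "need 0 < lcl < ucl")
      else if (!(r$reported_lcl <= r$reported_or &&
                 r$reported_or <= r$reported_ucl))
        flag(i, "reported_ci", "reported OR outside its own CI")
      if (nzchar(r$reported_model) && !r$reported_model %in% genetic_models)
        flag(i, "reported_model",
             paste0("unknown genetic model '", r$reported_model, "'"))
    }
  }
  if (length(bad) == 0L)
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

#' Write a study table
#'
#' Inverse of [read_study_table()]: UTF-8, comma-separated, quoted strings,
#' empty fields for missing values, so that read -> write -> read
#' round-trips to identical records.
#'
#' @param records A `study_table`.
#' @param path Output CSV path.
#' @param include_truth Keep non-schema columns (e.g. the simulator's hidden
#'   `true_log_or`)? Default drops them.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path, include_truth = FALSE) {
  out <- as.data.frame(records)
  keep <- if (include_truth) {
    c(study_table_columns, setdiff(names(out), study_table_columns))
  } else {
    study_table_columns
  }
  out <- out[, intersect(keep, names(out)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Classify studies as small or large by case count
#'
#' A study is `"large"` when it has more than 200 cases, otherwise
#' `"small"` (a study with exactly 200 cases is small).
#'
#' @param n_cases Numeric vector of case counts, or a `study_table` (its
#'   `n_cases` column is used).
#' @return Character vector of `"small"` / `"large"` labels.
#' @export
classify_sample_size <- function(n_cases) {
  if (is.data.frame(n_cases)) n_cases <- n_cases$n_cases
  stopifnot(all(n_cases >= 1))
  ifelse(n_cases > 200, "large", "small")
}

study_label <- function(records) {
  paste(records$author, records$year)
}

#' Per-study effect estimates from a study table
#'
#' Derives one log odds ratio and standard error per row: from the genotype
#' counts collapsed under the requested genetic model when all six counts
#' are present, otherwise from the reported OR and 95% CI
#' (see [effect_from_reported()]).
#'
#' @param records A `study_table`.
#' @param model Genetic model (`"recessive"` or `"dominant"`) used to
#'   collapse genotype counts; defaults to each row's `reported_model`.
#' @param correction Continuity correction for zero cells, passed to
#'   [odds_ratio_from_2x2()].
#' @return An `effect_table` data.frame: `label`, `snp_id`, `y`, `se`,
#'   OR-scale columns, stratification metadata and `k_members` (1 for raw
#'   rows; >1 after [aggregate_shared_controls()]).
#' @export
study_effects <- function(records, model = NULL, correction = 0.5) {
  stopifnot(nrow(records) > 0L)
  n <- nrow(records)
  y <- se <- numeric(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    counts <- unlist(r[genotype_columns])
    if (all(!is.na(counts))) {
      m <- if (!is.null(model)) model else r$reported_model
      if (!m %in% c("recessive", "dominant"))
        stop("row ", i, ": no usable genetic model for genotype counts")
      tab <- collapse_genotypes(counts, m)
      est <- odds_ratio_from_2x2(tab[1], tab[2], tab[3], tab[4],
                                 correction = correction)
    } else {
      est <- effect_from_reported(r$reported_or, r$reported_lcl,
                                  r$reported_ucl)
    }
    y[i] <- est$y
    se[i] <- est$se
  }
  out <- data.frame(
    label = study_label(records),
    snp_id = records$snp_id,
    y = y, se = se,
    or = exp(y), lcl = exp(y - 1.96 * se), ucl = exp(y + 1.96 * se),
    tumour_site = records$tumour_site,
    ethnicity = records$ethnicity,
    design = records$design,
    n_cases = records$n_cases,
    n_controls = records$n_controls,
    sample_size = classify_sample_size(records$n_cases),
    shared_control_group = records$shared_control_group,
    k_members = 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Merge study strata that reuse one control series
#'
#' Rows sharing a non-empty `shared_control_group` key (within one SNP) are
#' merged into a single analysis unit so the shared controls are not counted
#' repeatedly in the overall pool. The member log odds ratios are combined
#' by a DerSimonian-Laird random-effects pool (the default), which reduces
#' to the inverse-variance fixed-effect combination when the members are
#' homogeneous. Member genotype counts are not needed. Tumour-site
#' stratified analyses bypass this step (the strata are distinct there).
#'
#' @param effects An `effect_table` from [study_effects()].
#' @param method `"dl"` (default) or `"fixed"` combination of member
#'   log odds ratios. The default reproduces the published overall pooled
#'   estimate; see the methods vignette.
#' @return An `effect_table` of analysis units; unkeyed rows pass through
#'   unchanged, in their original order, merged units appended per group.
#' @export
aggregate_shared_controls <- function(effects, method = c("dl", "fixed")) {
  method <- match.arg(method)
  keyed <- nzchar(effects$shared_control_group)
  if (!any(keyed)) return(effects)
  out <- effects[!keyed, , drop = FALSE]
  groups <- split(effects[keyed, , drop = FALSE],
                  paste(effects$snp_id[keyed],
                        effects$shared_control_group[keyed]))
  for (g in groups) {
    if (nrow(g) == 1L) {
      message("shared-control group '", g$shared_control_group,
              "' has a single member; passing through")
      out <- rbind(out, g)
      next
    }
    pooled <- if (method == "dl") {
      random_effects_pool(g$y, g$se)
    } else {
      fixed_effect_pool(g$y, g$se)
    }
    unit <- g[1, , drop = FALSE]
    unit$label <- paste0(unique(g$shared_control_group),
                         " (", nrow(g), " strata)")
    unit$y <- pooled$y_pooled
    unit$se <- pooled$se_pooled
    unit$or <- exp(unit$y)
    unit$lcl <- exp(unit$y - 1.96 * unit$se)
    unit$ucl <- exp(unit$y + 1.96 * unit$se)
    unit$tumour_site <- if (length(unique(g$tumour_site)) == 1L)
      g$tumour_site[1] else NA_character_
    unit$n_cases <- sum(g$n_cases)
    unit$n_controls <- max(g$n_controls)  # one shared series, counted once
    unit$sample_size <- classify_sample_size(unit$n_cases)
    unit$k_members <- nrow(g)
    out <- rbind(out, unit)
  }
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  out
}
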