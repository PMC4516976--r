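#' Read a PED-like family table
#'
#' Reads a whitespace/tab-delimited family table with a header line.
#' Required columns: `family_id`, `subject_id`, `father_id`, `mother_id`,
#' `sex`, `age`; the phenotype/genotype columns `X` (allele count 0/1/2),
#' `E` (exposure), `Y1`, `Y2` (0/1) and any extra columns are kept when
#' present.  `"0"` denotes a missing parent and `"NA"` a missing value.
#' Lines starting with `#` are ignored.  Parent references are validated
#' within each family and domain values are checked, with offending line
#' numbers reported.
#'
#' @param path Path to the file.
#' @return The family dataset data frame, with the reconstructed pedigree
#'   list attached as attribute `"pedigrees"`.
#' @export
read_family_table <- function(path) {
  if (!file.exists(path))
    jx_stop(sprintf("file not found: %s", path), "jx_parse_error")
  dat <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = NA, na.strings = "NA")
  required <- c("family_id", "subject_id", "father_id", "mother_id",
                "sex", "age")
  miss <- setdiff(required, names(dat))
  if (length(miss))
    jx_stop(sprintf("missing required column(s): %s",
                    paste(miss, collapse = ", ")), "jx_parse_error")
  for (col in c("family_id", "subject_id", "father_id", "mother_id"))
    dat[[col]] <- as.character(dat[[col]])
  dat$father_id <- .norm_parent(dat$father_id)
  dat$mother_id <- .norm_parent(dat$mother_id)
  line_no <- seq_len(nrow(dat)) + 1L          # header is line 1
  .check_domain <- function(col, allowed) {
    if (!col %in% names(dat)) return()
    bad <- !is.na(dat[[col]]) & !dat[[col]] %in% allowed
    if (any(bad))
      jx_stop(sprintf("column %s has values outside {%s} at line(s) %s",
                      col, paste(allowed, collapse = ","),
                      paste(utils::head(line_no[bad], 5), collapse = ", ")),
              "jx_parse_error")
  }
  .check_domain("X", 0:2)
  .check_domain("X_null", 0:2)
  .check_domain("Y1", 0:1)
  .check_domain("Y2", 0:1)
  ## parent resolution, per family, with line numbers
  for (fam in unique(dat$family_id)) {
    rows <- which(dat$family_id == fam)
    ids <- dat$subject_id[rows]
    for (pc in c("father_id", "mother_id")) {
      p <- dat[[pc]][rows]
      bad <- !is.na(p) & !p %in% ids
      if (any(bad))
        jx_stop(sprintf("family %s: %s %s not found among family members (line %d)",
                        fam, pc, p[bad][1], line_no[rows[bad][1]]),
                "jx_parse_error")
    }
  }
  peds <- .peds_from_dataset(dat)
  attr(dat, "pedigrees") <- peds
  dat
}

#' Write a family dataset as a PED-like table
#'
#' Tab-separated, header line, `"0"` for missing parents, `"NA"` for
#' missing values; a comment line carrying the configuration hash is
#' prepended when a scenario is attached to the dataset.
#'
#' @param dat Family dataset (e.g. from [simulate_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(dat, path) {
  out <- as.data.frame(dat)
  out$father_id[is.na(out$father_id)] <- "0"
  out$mother_id[is.na(out$mother_id)] <- "0"
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(dat, "scenario")
  if (!is.null(cfg))
    writeLines(sprintf("# jointGxE dataset; config_hash %s; scenario %s/%s; seed %d",
                       config_hash(cfg), cfg$generating_model,
                       cfg$exposure_kind, cfg$seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Prevalence audit of a family dataset
#'
#' Marginal prevalences (in percent) of the endophenotype, the disease,
#' the disease within endophenotype strata, and of any additional binary
#' 0/1 columns, computed over non-missing values.
#'
#' @param dat Family dataset with columns `Y1`, `Y2` and optionally other
#'   binary columns.
#' @param extra_columns Extra binary columns to audit (default: all
#'   columns beyond the standard ones whose non-missing values are 0/1).
#' @return Named numeric vector of percentages.
#' @export
prevalence_audit <- function(dat, extra_columns = NULL) {
  pct <- function(x) 100 * mean(x, na.rm = TRUE)
  out <- c(endophenotype = pct(dat$Y1),
           disease = pct(dat$Y2),
           disease_given_endophenotype = pct(dat$Y2[dat$Y1 == 1]),
           disease_given_no_endophenotype = pct(dat$Y2[dat$Y1 == 0]))
  std <- c("family_id", "subject_id", "father_id", "mother_id", "sex",
           "age", "X", "X_null", "E", "Y1", "Y2")
  if (is.null(extra_columns)) {
    extra_columns <- setdiff(names(dat), std)
    extra_columns <- extra_columns[vapply(extra_columns, function(cc)
      all(stats::na.omit(dat[[cc]]) %in% 0:1), logical(1))]
  }
  for (cc in extra_columns) out[cc] <- pct(dat[[cc]])
  out
}

#' Hash of a configuration object
#'
#' MD5 digest of the serialized object, used to stamp output files for
#' provenance.
#'
#' @param x Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  x$seed <- NULL                       # hash identifies the settings
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Read a run/scenario configuration file
#'
#' YAML key-value configuration.  Recognized keys: `generating_model`,
#' `exposure_kind`, `n_families`, `maf`, `seed`, `null_variant`,
#' `random_sd`, `exposure_sd`, `exposure_age_slope`, `coefficients`
#' (nested blocks `alpha`, `gamma`, `beta`), `targets`.  Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    jx_stop(sprintf("file not found: %s", path), "jx_parse_error")
  y <- yaml::read_yaml(path)
  known <- c("generating_model", "exposure_kind", "n_families", "maf",
             "seed", "null_variant", "random_sd", "exposure_sd",
             "exposure_age_slope", "coefficients", "targets")
  bad <- setdiff(names(y), known)
  if (length(bad))
    jx_stop(sprintf("unknown configuration key(s): %s",
                    paste(bad, collapse = ", ")), "jx_config_error")
  if (!is.null(y$coefficients))
    y$coefficients <- lapply(y$coefficients, function(b)
      if (is.list(b) && !is.null(b$rows)) {
        m <- do.call(rbind, b$values); dimnames(m) <- list(b$rows, b$cols); m
      } else unlist(b))
  if (!is.null(y$random_sd)) y$random_sd <- unlist(y$random_sd)
  if (!is.null(y$targets)) y$targets <- unlist(y$targets)
  do.call(scenario_config, y)
}

## serialize a fit to a JSON-ready list
.fit_json <- function(fit) {
  fc <- .fit_core(fit)
  core <- fc$core
  list(kind = fc$kind,
       terms = names(core$coefficients),
       estimate = unname(core$coefficients),
       robust_se = unname(sqrt(diag(core$robust_vcov))),
       naive_se = unname(sqrt(diag(core$naive_vcov))),
       robust_vcov = unname(core$robust_vcov),
       n_obs = core$n_obs, n_clusters = core$n_clusters,
       iterations = core$iterations, converged = core$converged)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a simulated family dataset),
#' `fit` (fit one analysis model to a family table, write coefficient JSON
#' and an effects TSV), `study` (replicate study, write the summary TSV
#' and a metadata JSON).  Run with no arguments for usage.  Returns the
#' exit code rather than quitting, so it can be driven from a wrapper
#' script (see `system.file("cli", "jointgxe.R", package = "jointGxE")`).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code: 0 success, 1 data/computation error, 2 usage
#'   error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: jointgxe <subcommand> [options]",
    "  simulate --scenario <transition1|transition2|polytomous>",
    "           [--exposure dichotomous|continuous] [--families N]",
    "           [--seed S] [--calib-n N] --out FILE",
    "  fit      --data FILE --model <transition|polytomous|disease-only>",
    "           [--workcorr independence|relationship] [--q1 Q --q3 Q]",
    "           --out PREFIX",
    "  study    --scenario <...> [--exposure ...] [--families N]",
    "           [--reps R] [--seed S] [--calib-n N] [--coverage true|false]",
    "           --out PREFIX",
    sep = "\n")
  if (!length(argv) || !argv[1] %in% c("simulate", "fit", "study")) {
    message(usage); return(2L)
  }
  tryCatch({
    opt <- .parse_argv(argv[-1])
    switch(argv[1],
           simulate = .cli_simulate(opt),
           fit = .cli_fit(opt),
           study = .cli_study(opt))
    0L
  },
  jx_argument_error = function(e) { message("usage error: ", conditionMessage(e)); 2L },
  jx_config_error = function(e) { message("usage error: ", conditionMessage(e)); 2L },
  jx_error = function(e) { message("error: ", conditionMessage(e)); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
}

.parse_argv <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      jx_stop(sprintf("unexpected argument '%s'", a), "jx_argument_error")
    if (i == length(args))
      jx_stop(sprintf("option %s needs a value", a), "jx_argument_error")
    opt[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}

.opt <- function(opt, name, default = NULL, required = FALSE) {
  v <- opt[[name]]
  if (is.null(v)) {
    if (required)
      jx_stop(sprintf("missing required option --%s", name),
              "jx_argument_error")
    return(default)
  }
  v
}

.cli_simulate <- function(opt) {
  cfg <- scenario_config(
    generating_model = .opt(opt, "scenario", required = TRUE),
    exposure_kind = .opt(opt, "exposure", "dichotomous"),
    n_families = as.integer(.opt(opt, "families", "223")),
    seed = as.integer(.opt(opt, "seed", "1")))
  out <- .opt(opt, "out", required = TRUE)
  message(sprintf("calibrating scenario %s (%s exposure) ...",
                  cfg$generating_model, cfg$exposure_kind))
  calib_n <- .opt(opt, "calib-n")
  cfg <- calibrate_intercepts(cfg,
                              n = if (!is.null(calib_n)) as.integer(calib_n))
  dat <- simulate_dataset(cfg)
  write_family_table(dat, out)
  message(sprintf("wrote %d subjects in %d families to %s",
                  nrow(dat), length(unique(dat$family_id)), out))
}

.cli_fit <- function(opt) {
  dat <- read_family_table(.opt(opt, "data", required = TRUE))
  model <- .opt(opt, "model", required = TRUE)
  workcorr <- .opt(opt, "workcorr", "independence")
  out <- .opt(opt, "out", required = TRUE)
  fit <- switch(model,
                transition = fit_transition(dat, workcorr),
                polytomous = fit_polytomous(dat),
                "disease-only" = fit_disease_only(dat, workcorr),
                jx_stop(sprintf("unknown model '%s'", model),
                        "jx_argument_error"))
  dichot <- length(unique(dat$E[!is.na(dat$E)])) <= 2
  if (dichot) {
    levels_e <- c(0, 1)
    m <- 2L * .n_equations(.fit_core(fit))
  } else {
    q1 <- as.numeric(.opt(opt, "q1",
                          stats::quantile(dat$E, 0.25, na.rm = TRUE)))
    q3 <- as.numeric(.opt(opt, "q3",
                          stats::quantile(dat$E, 0.75, na.rm = TRUE)))
    levels_e <- c(q1, q3)
    m <- 2L * .n_equations(.fit_core(fit))
  }
  labels <- if (model == "transition")
    c("MetS (normal WC)", "MetS (elevated WC)") else NULL
  tab <- effects_table(fit, levels_e, m = m, stratum_labels = labels)
  num <- vapply(tab, is.numeric, logical(1)) & !names(tab) %in%
    c("p_raw", "p_adjusted")
  tab[num] <- lapply(tab[num], round, 4)
  tab$p_raw <- signif(tab$p_raw, 3); tab$p_adjusted <- signif(tab$p_adjusted, 3)
  js <- .fit_json(fit)
  js$config_hash <- config_hash(list(model = model, workcorr = workcorr))
  jsonlite::write_json(js, paste0(out, "_fit.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(tab, paste0(out, "_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf("wrote %s_fit.json and %s_effects.tsv", out, out))
}

.cli_study <- function(opt) {
  cfg <- scenario_config(
    generating_model = .opt(opt, "scenario", required = TRUE),
    exposure_kind = .opt(opt, "exposure", "dichotomous"),
    n_families = as.integer(.opt(opt, "families", "223")),
    seed = as.integer(.opt(opt, "seed", "1")))
  n_reps <- as.integer(.opt(opt, "reps", "1000"))
  out <- .opt(opt, "out", required = TRUE)
  calib_n <- .opt(opt, "calib-n")
  cfg <- calibrate_intercepts(cfg,
                              n = if (!is.null(calib_n)) as.integer(calib_n))
  summ <- run_study(cfg, n_reps = n_reps,
                    coverage = tolower(.opt(opt, "coverage", "true")) == "true")
  tab <- as.data.frame(summ)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 4)
  utils::write.table(tab, paste0(out, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(config_hash = config_hash(cfg), seed = cfg$seed,
               n_reps = n_reps, generating_model = cfg$generating_model,
               exposure_kind = cfg$exposure_kind,
               package_version = as.character(utils::packageVersion("jointGxE")),
               r_version = R.version.string)
  jsonlite::write_json(meta, paste0(out, "_meta.json"), auto_unbox = TRUE)
  message(sprintf("wrote %s_summary.tsv and %s_meta.json", out, out))
}
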