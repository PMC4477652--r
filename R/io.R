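# Delimited-text readers/writers and the YAML run configuration. Files hold
# temperatures in degrees Celsius (the reporting convention); everything
# internal is Kelvin. All writers embed provenance (package version, seed,
# config hash) so every artifact can be traced to its run.

.read_delim_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0)
    stop("no data rows in ", path, call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read an exchange-rate table
#'
#' TSV with header `label  T_C  c_cat_mM  k_ex_s  sigma_s`. Rows are grouped
#' by label into [exchange_series()] objects. Malformed rows (non-numeric or
#' missing values, non-positive sigma) and duplicate `(label, T, c)`
#' combinations are rejected with the offending line numbers. A file with a
#' single catalyst concentration loads fine; [fit_base_pair()] will refuse it
#' later.
#'
#' @param path file path.
#' @return named list of [exchange_series()].
#' @export
read_rate_table <- function(path) {
  df <- .read_delim_checked(path, c("label", "T_C", "c_cat_mM", "k_ex_s",
                                    "sigma_s"))
  num <- c("T_C", "c_cat_mM", "k_ex_s", "sigma_s")
  bad <- !stats::complete.cases(df[num]) |
    !vapply(seq_len(nrow(df)),
            function(i) all(is.finite(as.numeric(df[i, num]))), logical(1)) |
    df$sigma_s <= 0
  if (any(bad))
    stop("malformed rate row(s) at line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  key <- paste(df$label, df$T_C, df$c_cat_mM)
  if (anyDuplicated(key))
    stop("duplicate (label, T, c_cat) row(s) at line(s): ",
         paste(which(duplicated(key)) + 1L, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$label), function(g)
    exchange_series(g$label[1], celsius_to_kelvin(g$T_C), g$c_cat_mM * 1e-3,
                    g$k_ex_s, g$sigma_s))
  out[unique(df$label)]
}

#' Write an exchange-rate table
#'
#' @param series list of [exchange_series()] (or a single one).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(series, path) {
  if (inherits(series, "exchange_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s)
    data.frame(label = s$label, T_C = kelvin_to_celsius(s$data$T),
               c_cat_mM = s$data$c_cat * 1e3, k_ex_s = s$data$k_ex,
               sigma_s = s$data$sigma)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read inversion-recovery profiles
#'
#' TSV with header `label  T_C  c_cat_mM  t_m_s  intensity_ratio`; one
#' profile per `(label, T, c)` group.
#'
#' @param path file path.
#' @return list of [ir_profile()].
#' @export
read_ir_profiles <- function(path) {
  df <- .read_delim_checked(path, c("label", "T_C", "c_cat_mM", "t_m_s",
                                    "intensity_ratio"))
  groups <- split(df, paste(df$label, df$T_C, df$c_cat_mM))
  out <- lapply(groups, function(g) {
    g <- g[order(g$t_m_s), ]
    ir_profile(g$label[1], celsius_to_kelvin(g$T_C[1]), g$c_cat_mM[1] * 1e-3,
               g$t_m_s, g$intensity_ratio)
  })
  unname(out)
}

#' Write inversion-recovery profiles
#'
#' @param profiles list of [ir_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ir_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(label = p$label, T_C = kelvin_to_celsius(p$T),
               c_cat_mM = p$c_cat * 1e3, t_m_s = p$t_m,
               intensity_ratio = p$intensity_ratio)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a CD melting curve
#'
#' CSV with header `T_C, ellipticity_mdeg`.
#'
#' @param path file path.
#' @param label construct name attached to the curve.
#' @return [read_melting_csv()]: a [melting_curve()];
#'   [write_melting_csv()]: `path`, invisibly.
#' @export
read_melting_csv <- function(path, label = basename(path)) {
  df <- .read_delim_checked(path, c("T_C", "ellipticity_mdeg"), sep = ",")
  df <- df[order(df$T_C), ]
  melting_curve(celsius_to_kelvin(df$T_C), df$ellipticity_mdeg, label = label)
}

#' @rdname read_melting_csv
#' @param curve a [melting_curve()].
#' @export
write_melting_csv <- function(curve, path) {
  utils::write.table(
    data.frame(T_C = kelvin_to_celsius(curve$T),
               ellipticity_mdeg = curve$signal),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_keys <- c("catalysis", "fit", "reporting")
.catalysis_keys <- c("dH_tr_ntp", "dS_tr_ntp", "d_dif", "c_ref",
                     "reference_species", "unc")
.fit_keys <- c("n_starts", "mc_iterations", "seed", "bounds")
.reporting_keys <- c("reference_T_C")

#' Read and validate a run configuration
#'
#' YAML with the top-level sections `catalysis` (see [catalysis_model()]),
#' `fit` (`n_starts`, `mc_iterations`, `seed`, optional `bounds` as a named
#' list of `[lower, upper]` pairs) and `reporting` (`reference_T_C`, default
#' 20). Unknown keys anywhere are rejected. The returned object carries the
#' MD5 hash of the file so that downstream reports can embed it.
#'
#' @param path YAML file path.
#' @return list with `catalysis` ([catalysis_model()]), `fit`
#'   ([global_fit_config()]), `reference_T_C`, `hash`, `path`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  .reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  .reject_unknown(raw, .config_keys, "top level")
  .reject_unknown(raw$catalysis, .catalysis_keys, "catalysis")
  .reject_unknown(raw$fit, .fit_keys, "fit")
  .reject_unknown(raw$reporting, .reporting_keys, "reporting")

  cat_args <- raw$catalysis %||% list()
  cat <- do.call(catalysis_model, cat_args)
  fit_raw <- raw$fit %||% list()
  bounds <- .default_bounds()
  for (nm in names(fit_raw$bounds)) {
    if (!nm %in% rownames(bounds))
      stop("unknown bounds parameter: ", nm, call. = FALSE)
    bounds[nm, ] <- as.numeric(fit_raw$bounds[[nm]])
  }
  cfg <- global_fit_config(bounds = bounds,
                           n_starts = fit_raw$n_starts %||% 7,
                           mc_iterations = fit_raw$mc_iterations %||% 200,
                           seed = fit_raw$seed %||% 20150504,
                           catalysis = cat)
  list(catalysis = cat, fit = cfg,
       reference_T_C = (raw$reporting %||% list())$reference_T_C %||% 20,
       hash = unname(tools::md5sum(path)), path = path)
}

.provenance <- function(seed = NA, config_hash = NA) {
  list(package = "rnathermo",
       version = as.character(utils::packageVersion("rnathermo")),
       seed = seed, config_hash = config_hash)
}

#' Write per-base-pair results as JSON
#'
#' Serialises fitted [base_pair_thermo()] objects (with their Monte Carlo
#' errors and, when supplied, confidence ellipses) together with run
#' provenance.
#'
#' @param bps list of [base_pair_thermo()].
#' @param path output JSON path.
#' @param ensembles optional named list of [mc_errors()] ensembles.
#' @param seed,config_hash provenance fields.
#' @return `path`, invisibly.
#' @export
write_bp_results <- function(bps, path, ensembles = NULL, seed = NA,
                             config_hash = NA) {
  recs <- lapply(bps, function(b) {
    r <- list(label = b$label, dH_diss = b$dH_diss, dS_diss = b$dS_diss,
              dH_tr_int = b$dH_tr_int, dS_tr_int = b$dS_tr_int, d = b$d,
              dG20 = gibbs_energy(293.15, b$dH_diss, b$dS_diss),
              averaged = b$averaged, err = b$err, flags = I(b$flags))
    ens <- ensembles[[b$label]]
    if (!is.null(ens))
      r$ellipse <- list(center = ens$ellipse$center, axes = ens$ellipse$axes,
                        orientation = ens$ellipse$orientation,
                        corr_HS = ens$corr_HS)
    r
  })
  jsonlite::write_json(list(provenance = .provenance(seed, config_hash),
                            base_pairs = unname(recs)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read per-base-pair results written by [write_bp_results()]
#'
#' @param path JSON path.
#' @return data frame with one row per base pair (columns `label`, `dH_diss`,
#'   `dS_diss`, `dH_tr_int`, `dS_tr_int`, `d`, `dG20`, `err_dH`, `err_dS`,
#'   `err_dG20`).
#' @export
read_bp_results <- function(path) {
  x <- jsonlite::read_json(path)
  do.call(rbind, lapply(x$base_pairs, function(r)
    data.frame(label = r$label, dH_diss = r$dH_diss, dS_diss = r$dS_diss,
               dH_tr_int = r$dH_tr_int, dS_tr_int = r$dS_tr_int, d = r$d,
               dG20 = r$dG20,
               err_dH = r$err$dH %||% NA_real_,
               err_dS = r$err$dS %||% NA_real_,
               err_dG20 = r$err$dG20 %||% NA_real_)))
}

#' Write a stability summary table
#'
#' A publication-shaped TSV: per base pair the opening enthalpy and entropy
#' with their Monte Carlo errors and the Gibbs energy at the reference
#' temperature.
#'
#' @param bps list of [base_pair_thermo()].
#' @param path output TSV path.
#' @param reference_T_C reference temperature for the Gibbs column, degC.
#' @return the summary data frame, invisibly.
#' @export
write_thermo_table <- function(bps, path, reference_T_C = 20) {
  TK <- celsius_to_kelvin(reference_T_C)
  df <- do.call(rbind, lapply(bps, function(b)
    data.frame(label = b$label,
               dH_diss = b$dH_diss, err_dH = b$err$dH,
               dS_diss = b$dS_diss, err_dS = b$err$dS,
               dG_ref = gibbs_energy(TK, b$dH_diss, b$dS_diss),
               err_dG_ref = b$err$dG20,
               flags = paste(b$flags, collapse = ";"))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
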