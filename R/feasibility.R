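#' Run a full feasibility assessment from a study-description file
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) study
#' description and composes the package's operations into a single
#' feasibility report: ICC extrapolation to the planned sample, threshold
#' classification, smallest detectable differences, correlation-power
#' feasibility under attenuation, group-difference attenuation, and the
#' required group separation for target reliabilities.
#'
#' ## Study-description schema
#' Required blocks:
#' \describe{
#'   \item{`trt`}{`{mean, sd, icc, n, k?, sem?}` — the published
#'     test-retest summary. An explicit `sem` overrides the one derived
#'     from `sd` and `icc`.}
#'   \item{`new`}{the planned sample's variability: one of `sd`,
#'     `sd_ratio`, or `groups` (a list of two `{n, mean, sd}` blocks whose
#'     pooled SD is computed with [combined_sample_sd()]).}
#' }
#' Optional blocks: `tau` (scalar, default 1); `sdd`
#' `{sigma_e?, conf?, n_group?}` (defaults: the tau-inflated SEM, 0.95, 2);
#' `power` `{rel_other, max_r2_biological, alpha?, power?, sides?}`;
#' `effect` `{d_true, n1?, n2?}`; `required_d`
#' `{targets, n1, n2, sd_ratio_2to1?}`; `overlap` `{d}`.
#'
#' @param study_file path to a `.json`, `.yaml` or `.yml` file.
#' @return an object of class `"feasibility_result"`; its list structure
#'   serializes directly to JSON via [feasibility_json()].
#' @examples
#' f <- system.file("extdata", "examples", "example1_extrapolation.json",
#'                  package = "relex")
#' run_feasibility(f)
#' @export
run_feasibility <- function(study_file) {
  study <- read_study_file(study_file)
  study <- validate_study(study)

  trt <- trt_summary(mean = study$trt$mean, sd = study$trt$sd,
                     icc = study$trt$icc, n = study$trt$n,
                     k = study$trt$k %||% 2L, sem = study$trt$sem)
  tau <- study$tau %||% 1

  # planned-sample SD
  groups <- NULL
  if (!is.null(study$new$groups)) {
    groups <- lapply(study$new$groups, function(g) group_spec(g$n, g$mean, g$sd))
    sd_new <- combined_sample_sd(groups[[1]], groups[[2]])
  } else if (!is.null(study$new[["sd"]])) {
    sd_new <- study$new[["sd"]]
  } else {
    sd_new <- study$new$sd_ratio * trt$sd
  }

  ex <- extrapolate_icc(trt, sd_new = sd_new, tau = tau)
  flags <- ex$flags

  sdd_conf <- study$sdd$conf %||% 0.95
  sdd_n <- study$sdd$n_group %||% 2L
  sigma_e <- study$sdd$sigma_e %||% ex$sem_used

  result <- list(
    extrapolated_icc = ex$icc_new,
    sem_used = ex$sem_used,
    sd_new = sd_new,
    classification = list(
      koo_li = classify_reliability(min(ex$icc_new, 1), "koo_li"),
      cicchetti = classify_reliability(min(ex$icc_new, 1), "cicchetti")
    ),
    sdd_individual = sdd_individual(sigma_e, sdd_conf),
    sdd_group = sdd_group(sigma_e, sdd_n, sdd_conf),
    sdd_n_group = sdd_n,
    flags = flags
  )

  if (!is.null(study$power)) {
    if (ex$icc_new <= 0) {
      result$flags <- c(result$flags,
        "correlation feasibility skipped: extrapolated reliability <= 0")
    } else {
      fc <- feasibility_correlation(
        rel_outcome = min(ex$icc_new, 1),
        rel_other = study$power$rel_other %||% 1,
        max_r2_biological = study$power$max_r2_biological %||% 1,
        alpha = study$power$alpha %||% 0.05,
        power = study$power$power %||% 0.8,
        sides = study$power$sides %||% "two"
      )
      result$attenuation <- fc$attenuation
      result$r_max <- fc$r_max
      result$r_observed <- fc$r_observed
      result$n_unattenuated <- fc$n_unattenuated$n_required
      result$n_required <- fc$n_required$n_required
      result$power_convention <- fc$n_required$convention
    }
  }

  if (!is.null(study$effect)) {
    if (ex$icc_new <= 0) {
      result$flags <- c(result$flags,
        "effect-size attenuation skipped: extrapolated reliability <= 0")
    } else {
      n1 <- study$effect$n1 %||% 1L
      n2 <- study$effect$n2 %||% 1L
      result$d_true <- study$effect$d_true
      result$d_observed <- attenuate_d(study$effect$d_true,
                                       min(ex$icc_new, 1), n1, n2)
    }
  }

  if (!is.null(study$required_d)) {
    rd <- study$required_d
    req <- lapply(rd$targets, function(tgt) {
      r <- required_d_for_reliability(trt, rd$n1, rd$n2, tgt, tau,
                                      rd$sd_ratio_2to1 %||% 1)
      list(target_icc = tgt, d = r$d, mu2 = r$mu2,
           sd_total_required = r$sd_total_required)
    })
    result$required_d <- req
  }

  if (!is.null(study$overlap)) {
    ov <- overlap_summary(study$overlap$d)
    result$overlap <- list(d = ov$d, u3 = ov$u3, ovl = ov$ovl, cles = ov$cles)
  }

  result$provenance <- list(
    study_file = normalizePath(study_file),
    trt = list(mean = trt$mean, sd = trt$sd, icc = trt$icc, n = trt$n,
               k = trt$k, sem = trt$sem, sem_explicit = trt$sem_explicit),
    tau = tau,
    sdd = list(sigma_e = sigma_e, conf = sdd_conf, n_group = sdd_n),
    assumptions = extrapolation_assumptions(),
    conventions = c(
      "correlation n: Fisher z, round-to-nearest",
      "t-test n: exact noncentral t, smallest integer reaching power",
      "SEM inflation tau multiplies the SEM (variance scales by tau^2)"
    )
  )
  class(result) <- "feasibility_result"
  result
}

#' @export
print.feasibility_result <- function(x, digits = 4, ...) {
  cat("Study feasibility assessment\n")
  cat(sprintf("  extrapolated ICC = %s (%s)\n",
              format(x$extrapolated_icc, digits = digits),
              x$classification$koo_li))
  cat(sprintf("  SDD: %s (individual), %s (mean of %d)\n",
              format(x$sdd_individual, digits = digits),
              format(x$sdd_group, digits = digits), x$sdd_n_group))
  if (!is.null(x$n_required)) {
    cat(sprintf("  correlation power: attenuation %s, n %d -> %d\n",
                format(x$attenuation, digits = digits),
                x$n_unattenuated, x$n_required))
  }
  if (!is.null(x$d_observed)) {
    cat(sprintf("  effect size: true d %s -> observed d %s\n",
                format(x$d_true, digits = digits),
                format(x$d_observed, digits = digits)))
  }
  if (!is.null(x$required_d)) {
    for (r in x$required_d) {
      cat(sprintf("  required d for ICC %s: %s\n",
                  format(r$target_icc, digits = digits),
                  format(r$d, digits = digits)))
    }
  }
  for (f in x$flags) cat("  note: ", f, "\n", sep = "")
  invisible(x)
}

#' Serialize a feasibility result to JSON
#'
#' Numbers are written at full double precision; use the CLI's `--round`
#' for display rounding.
#'
#' @param result a `"feasibility_result"` object.
#' @param path optional output file; if omitted the JSON string is
#'   returned.
#' @return the JSON string (invisibly if written to `path`).
#' @export
feasibility_json <- function(result, path = NULL) {
  json <- jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

read_study_file <- function(path) {
  if (!file.exists(path)) {
    stop(schema_error(paste0("study file not found: ", path)))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop(schema_error("YAML study files need the 'yaml' package; use JSON instead"))
    }
    y <- yaml::read_yaml(path)
    fix_yaml_n_key(y)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) stop(schema_error(
               paste0("study file is not valid JSON: ", conditionMessage(e)))))
  }
}

validate_study <- function(study) {
  fail <- function(msg) stop(schema_error(msg))
  if (!is.list(study)) fail("study description must be a JSON/YAML object")
  if (is.null(study$trt)) fail("missing required block 'trt'")
  for (f in c("mean", "sd", "icc", "n")) {
    if (is.null(study$trt[[f]]) || !is.numeric(study$trt[[f]])) {
      fail(paste0("'trt$", f, "' must be a number"))
    }
  }
  if (is.null(study$new)) fail("missing required block 'new'")
  sources <- c(!is.null(study$new[["sd"]]), !is.null(study$new$sd_ratio),
               !is.null(study$new$groups))
  if (sum(sources) != 1) {
    fail("'new' must contain exactly one of 'sd', 'sd_ratio', 'groups'")
  }
  if (!is.null(study$new$groups)) {
    if (length(study$new$groups) != 2) fail("'new$groups' must list exactly two groups")
    for (g in study$new$groups) {
      for (f in c("n", "mean", "sd")) {
        if (is.null(g[[f]]) || !is.numeric(g[[f]])) {
          fail(paste0("each group needs numeric '", f, "'"))
        }
      }
    }
  }
  if (!is.null(study$required_d)) {
    for (f in c("targets", "n1", "n2")) {
      if (is.null(study$required_d[[f]])) fail(paste0("'required_d$", f, "' is required"))
    }
    study$required_d$targets <- unlist(study$required_d$targets)
  }
  if (!is.null(study$power) && is.null(study$power$max_r2_biological)) {
    fail("'power$max_r2_biological' is required in the power block")
  }
  study
}

# YAML 1.1 resolves a bare key `n` to boolean FALSE; `n` is a schema key
# (group size), so map the mangled name back wherever it appears.
fix_yaml_n_key <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "FALSE", "n", nm)
  lapply(x, fix_yaml_n_key)
}

schema_error <- function(msg) {
  structure(class = c("relex_schema_error", "error", "condition"),
            list(message = msg, call = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
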