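#' Build an analysis configuration
#'
#' Assembles and validates the configuration consumed by [run_analysis()].
#' Exactly one of `fasta` or `simulate` provides the input alignment.
#'
#' @param fasta path to an aligned FASTA file.
#' @param simulate a list of simulation parameters (`n`, `k`, `theta0`,
#'   `theta1`, `tau`, optional `kappa`, `model`) passed to [sim_alignment()].
#' @param groups `NULL` (one group `"all"`), a named list `label -> character
#'   vector of ids`, or the path to a two-column TSV (`id<TAB>group`). Group
#'   membership is analyst-assigned input, not computed.
#' @param scenarios a [calibration_scenarios()] preset name, a numeric vector
#'   of times (years), or a `data.frame` with `label`/`t_years`.
#' @param tau optional fixed expansion parameter: skips mismatch fitting and
#'   calibrates rates directly from this value.
#' @param g generation time in years.
#' @param reps replicates for the neutrality and bootstrap stages (>= 100).
#' @param seed master seed; required because the simulation, neutrality and
#'   bootstrap stages are stochastic. Per-stage child seeds are derived by a
#'   fixed rule so adding a stage never perturbs earlier streams.
#' @param drop_indels exclude gapped columns before analysis (default `TRUE`).
#' @param gof run the parametric-bootstrap goodness-of-fit stage.
#' @param outdir optional directory for `report.json`, TSV tables and (for
#'   simulated input) the FASTA plus truth sidecar.
#' @return A validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(fasta = NULL, simulate = NULL, groups = NULL,
                            scenarios = "postglacial", tau = NULL, g = 1,
                            reps = 1000, seed = NULL, drop_indels = TRUE,
                            gof = TRUE, outdir = NULL) {
  if (is.null(fasta) == is.null(simulate)) {
    stop("config error: exactly one of 'fasta' or 'simulate' must be given")
  }
  if (reps < 100) stop("config error: reps must be >= 100")
  if (is.null(seed)) stop("config error: a seed is required")
  if (is.character(groups) && length(groups) == 1L) {
    tab <- utils::read.table(groups, sep = "\t", header = FALSE,
                             col.names = c("id", "group"),
                             colClasses = "character")
    groups <- split(tab$id, tab$group)
  }
  if (!is.null(groups)) {
    if (length(groups) == 0L) stop("config error: no groups defined")
    ids <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(ids)) {
      stop("config error: sequence id assigned to more than one group")
    }
  }
  if (is.character(scenarios)) scenarios <- calibration_scenarios(scenarios)
  if (is.numeric(scenarios)) {
    scenarios <- data.frame(label = paste0(scenarios / 1000, " kyr"),
                            t_years = scenarios)
  }
  structure(list(fasta = fasta, simulate = simulate, groups = groups,
                 scenarios = scenarios, tau = tau, g = g, reps = reps,
                 seed = as.integer(seed), drop_indels = isTRUE(drop_indels),
                 gof = isTRUE(gof), outdir = outdir),
            class = "analysis_config")
}

# Deterministic child-seed derivation: fixed stage offsets mean adding stages
# never shifts the streams of existing ones (internal).
child_seed <- function(seed, stage, group_index = 0L) {
  offsets <- c(simulate = 1L, neutrality = 2L, gof = 3L)
  (seed + 7919L * offsets[[stage]] + 104729L * group_index) %% 2147483647L
}

# Order-independent hash of the semantic configuration fields (internal):
# polynomial rolling hash over the canonical JSON serialization.
config_hash <- function(config) {
  semantic <- config[c("fasta", "simulate", "groups", "scenarios", "tau", "g",
                       "reps", "seed", "drop_indels", "gof")]
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) x <- lapply(x[order(names(x))], canon)
    x
  }
  s <- as.character(jsonlite::toJSON(canon(semantic), auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full expansion-rate analysis
#'
#' Orchestrates, per group: diversity summary, neutrality tests, mismatch fit
#' with goodness of fit, and rate calibration under the configured scenarios.
#' A stage failure (e.g. a monomorphic group) is recorded for that group
#' without aborting the others. Given the same configuration and seed the
#' report is reproducible byte for byte.
#'
#' @param config an [analysis_config()] (or a list/YAML path accepted by it:
#'   a character scalar is read with `yaml::read_yaml` and a plain list is
#'   passed to [analysis_config()] as arguments).
#' @return An `"analysis_report"`: per-group results plus a provenance block
#'   (`config_hash`, `seed`, package `version`). If `outdir` is set,
#'   `report.json` and TSV tables are written there.
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "analysis_config")) {
    config <- do.call(analysis_config, config)
  }
  sim <- NULL
  if (!is.null(config$simulate)) {
    sp <- config$simulate
    sim <- sim_alignment(n = sp$n, k = sp$k, theta0 = sp$theta0,
                         theta1 = sp$theta1, tau = sp$tau,
                         kappa = if (is.null(sp$kappa)) 10 else sp$kappa,
                         model = if (is.null(sp$model)) "k2p" else sp$model,
                         seed = child_seed(config$seed, "simulate"))
    aln <- sim$alignment
  } else {
    aln <- read_fasta(config$fasta)
  }
  if (config$drop_indels) aln <- exclude_indels(aln)
  groups <- config$groups
  if (is.null(groups)) groups <- list(all = aln$ids)
  miss <- setdiff(unlist(groups), aln$ids)
  if (length(miss)) {
    stop("config error: group ids absent from alignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }

  res <- list()
  gi <- 0L
  for (gname in names(groups)) {
    gi <- gi + 1L
    sub <- subset_alignment(aln, groups[[gname]])
    out <- list()
    out$diversity <- tryCatch(diversity_summary(sub),
                              error = function(e) list(error = conditionMessage(e)))
    out$neutrality <- tryCatch({
      nt <- neutrality_test(sub, reps = config$reps,
                            seed = child_seed(config$seed, "neutrality", gi))
      unclass(nt)[c("D", "Fs", "p_D", "p_Fs", "reps", "n", "S", "h")]
    }, error = function(e) list(error = conditionMessage(e)))
    tau_hat <- config$tau
    if (is.null(tau_hat)) {
      out$fit <- tryCatch({
        f <- sudden_expansion(sub)
        if (config$gof) {
          gt <- gof_test(f, reps = config$reps,
                         seed = child_seed(config$seed, "gof", gi))
          f$p_ssd <- gt$p_ssd
          f$p_r <- gt$p_r
        }
        tau_hat <- unname(coef(f)["tau"])
        list(tau = unname(coef(f)["tau"]), theta0 = unname(coef(f)["theta0"]),
             theta1 = unname(coef(f)["theta1"]), ssd = f$ssd,
             raggedness = f$raggedness, p_ssd = f$p_ssd, p_r = f$p_r,
             observed = f$observed$counts, fitted = f$fitted)
      }, error = function(e) list(error = conditionMessage(e)))
    } else {
      out$fit <- list(tau = tau_hat, note = "tau supplied; fitting bypassed")
    }
    out$rates <- if (!is.null(tau_hat)) {
      rate_table(tau_hat, config$scenarios, k = sub$k, g = config$g)
    } else {
      list(error = "no tau available (fit failed)")
    }
    res[[gname]] <- out
  }

  report <- structure(
    list(groups = res,
         provenance = list(config_hash = config_hash(config),
                           seed = config$seed,
                           version = as.character(utils::packageVersion("expansionclock")))),
    class = "analysis_report")
  if (!is.null(config$outdir)) {
    write_report(report, config, aln, sim)
  }
  report
}

# Serialize a report to outdir: report.json plus TSV tables (internal).
write_report <- function(report, config, aln, sim) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass_deep(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  grab <- function(field) {
    ok <- Filter(function(g) is.data.frame(g[[field]]) ||
                   (is.list(g[[field]]) && is.null(g[[field]]$error)),
                 report$groups)
    if (length(ok) == 0L) return(NULL)
    do.call(rbind, lapply(names(ok), function(nm) {
      cbind(group = nm, as.data.frame(ok[[nm]][[field]][
        !vapply(ok[[nm]][[field]], is.null, TRUE)]))
    }))
  }
  for (field in c("diversity", "neutrality", "rates")) {
    tab <- grab(field)
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(config$outdir, paste0(field, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (nm in names(report$groups)) {
    f <- report$groups[[nm]]$fit
    if (!is.null(f$observed)) {
      tab <- data.frame(class = seq_along(f$observed) - 1L,
                        observed = f$observed,
                        observed_freq = f$observed / sum(f$observed),
                        expected_freq = f$fitted)
      utils::write.table(tab,
                         file.path(config$outdir, paste0("mismatch_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(sim)) {
    write_fasta(sim$alignment, file.path(config$outdir, "simulated.fasta"))
    jsonlite::write_json(sim$truth, file.path(config$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(NULL)
}

# Strip S3 classes recursively for JSON serialization (internal).
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Expansion analysis report (", length(x$groups), " group(s); config ",
      x$provenance$config_hash, ", seed ", x$provenance$seed, ")\n", sep = "")
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat("\n== Group", nm, "==\n")
    if (!is.null(g$diversity$error)) {
      cat("  diversity: ERROR:", g$diversity$error, "\n")
    } else {
      d <- g$diversity
      cat(sprintf("  n=%d k=%d S=%d h=%d pi=%.3f%% Hd=%.3f\n",
                  d$n, d$k, d$S, d$h, d$pi_pct, d$hd))
    }
    if (is.null(g$neutrality$error)) {
      cat(sprintf("  Tajima's D=%.3f (p=%.3g)  Fu's Fs=%.3f (p=%.3g)\n",
                  g$neutrality$D, g$neutrality$p_D,
                  g$neutrality$Fs, g$neutrality$p_Fs))
    }
    if (is.null(g$fit$error) && !is.null(g$fit$tau)) {
      cat(sprintf("  tau=%.4g", g$fit$tau))
      if (!is.null(g$fit$ssd)) {
        cat(sprintf("  SSD=%.4g r=%.4g", g$fit$ssd, g$fit$raggedness))
        if (!is.null(g$fit$p_ssd)) {
          cat(sprintf("  p_SSD=%.3g p_r=%.3g", g$fit$p_ssd, g$fit$p_r))
        }
      }
      cat("\n")
      if (is.data.frame(g$rates)) {
        for (i in seq_len(nrow(g$rates))) {
          cat(sprintf("    %-26s t=%6d yr  mu=%5.1f %%/site/myr\n",
                      g$rates$label[i], g$rates$t_years[i],
                      g$rates$mu_rounded[i]))
        }
      }
    } else if (!is.null(g$fit$error)) {
      cat("  mismatch fit: ERROR:", g$fit$error, "\n")
    }
  }
  invisible(x)
}
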