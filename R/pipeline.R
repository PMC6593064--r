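# End-to-end orchestration: simulate -> associate -> scan -> thermo -> expr,
# with a combined JSON + Markdown report. All randomness flows through the
# single config seed; reports carry no timestamps so a fixed seed yields
# byte-identical output.

default_run_config <- function() {
  list(seed = 1L,
       out_dir = NULL,
       stages = c("simulate", "assoc", "scan", "thermo", "expr"),
       preset = NULL,
       genotype_counts_file = NULL,
       n_cases = 66L, n_controls = 42L,
       control_allele_freq = 0.357, allele_or = 1.8,
       per_risk_allele_shift = -0.3, noise_sd = 0.3,
       mirna_target_r2 = 0.255,
       window = 60L, gc_background = 0.5, mirna_len = 22L,
       snp_offset_in_seed = 3L,
       n_windows = 1L,
       alpha = 0.05,
       stack_file = NULL, loop_file = NULL)
}

#' Load and validate a pipeline run configuration
#'
#' @param config a named list of overrides, or the path of a YAML file
#'   holding them. Unknown keys are rejected; referenced files must exist.
#' @return The completed configuration list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  base <- default_run_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(config)] <- config
  if (!is.null(base$preset)) {
    if (base$preset == "table1") {
      base$stages <- "assoc"
      if (is.null(base$genotype_counts_file))
        base$genotype_counts_file <- system.file(
          "extdata", "table1_counts.tsv", package = "seedshift")
    } else if (base$preset != "sim")
      stop("unknown preset: ", base$preset, call. = FALSE)
  }
  if (length(base$stages) == 0L)
    stop("no stages enabled", call. = FALSE)
  bad <- setdiff(base$stages, default_run_config()$stages)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (f in c("genotype_counts_file", "stack_file", "loop_file"))
    if (!is.null(base[[f]]) && !file.exists(base[[f]]))
      stop(f, " does not exist: ", base[[f]], call. = FALSE)
  base$seed <- as.integer(base$seed)
  base
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — cohort simulation, association
#' testing, seed scanning, per-allele thermodynamics, expression analysis —
#' and writes `report.json` (validated against the bundled schema) plus a
#' human-readable `report.md` and per-stage tables into the output
#' directory. If a stage fails, outputs of completed stages are retained
#' along with a `manifest.json` naming them, and the error is re-signalled.
#'
#' @param config a config list or YAML path (see [load_run_config()]);
#'   `out_dir` is required.
#' @return The report list, invisibly.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "seedshift-demo")
#' run_pipeline(list(preset = "table1", out_dir = out, seed = 1))
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- if (!is.null(cfg$stack_file) || !is.null(cfg$loop_file)) {
    energy_model(
      stack_file = cfg$stack_file %||% system.file(
        "extdata", "nn_stacks.tsv", package = "seedshift"),
      loop_file = cfg$loop_file %||% system.file(
        "extdata", "loop_penalties.tsv", package = "seedshift"))
  } else default_energy_model()

  report <- list(seed = cfg$seed, stages_run = character(0),
                 results = list())
  state <- list()
  done <- function(stage) {
    report$stages_run <<- c(report$stages_run, stage)
    write_manifest(cfg$out_dir, report$stages_run)
  }

  run_stage <- function(stage, fn) {
    msg("stage: ", stage)
    tryCatch(fn(), error = function(e) {
      write_manifest(cfg$out_dir, report$stages_run, failed = stage)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("simulate" %in% cfg$stages) run_stage("simulate", function() {
    geno <- gen_genotypes(cfg$n_cases, cfg$n_controls,
                          cfg$control_allele_freq, cfg$allele_or,
                          seed = cfg$seed)
    expr <- gen_expression(geno,
                           per_risk_allele_shift = cfg$per_risk_allele_shift,
                           noise_sd = cfg$noise_sd,
                           mirna_target_r2 = cfg$mirna_target_r2,
                           seed = cfg$seed + 1L)
    win <- gen_snp_window(cfg$window, cfg$gc_background, cfg$mirna_len,
                          cfg$snp_offset_in_seed, seed = cfg$seed + 2L)
    utils::write.csv(geno, file.path(cfg$out_dir, "genotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(expr$ct, file.path(cfg$out_dir, "ct_table.csv"),
                     row.names = FALSE)
    write_fasta_sequences(list(win$window_ref, win$window_alt, win$mirna),
                          file.path(cfg$out_dir, "sequences.fa"))
    state$geno <<- geno; state$expr <<- expr; state$win <<- win
    done("simulate")
  })

  if ("assoc" %in% cfg$stages) run_stage("assoc", function() {
    rep <- if (!is.null(cfg$genotype_counts_file)) {
      build_table1(counts = read.delim(cfg$genotype_counts_file,
                                       comment.char = "#",
                                       stringsAsFactors = FALSE))
    } else if (!is.null(state$geno)) {
      build_table1(records = state$geno)
    } else stop("no genotype input: give genotype_counts_file or enable ",
                "the simulate stage")
    write.table(rep$formatted, file.path(cfg$out_dir, "association.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$results$assoc <<- assoc_report_json(rep)
    state$assoc <<- rep
    done("assoc")
  })

  if ("scan" %in% cfg$stages) run_stage("scan", function() {
    if (is.null(state$win)) stop("scan stage needs the simulate stage")
    w <- state$win
    cls <- classify_snp_effect(w$window_ref, w$snp, w$mirna)
    sites <- scan_seed_sites(w$window_alt, w$mirna)
    write.table(sites, file.path(cfg$out_dir, "seed_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$results$scan <<- list(
      effect = cls$effect, snp_in_seed = cls$snp_in_seed,
      ref_class = cls$ref_site$seed_class,
      alt_class = cls$alt_site$seed_class)
    state$scan <<- cls
    done("scan")
  })

  if ("thermo" %in% cfg$stages) run_stage("thermo", function() {
    if (is.null(state$win)) stop("thermo stage needs the simulate stage")
    w <- state$win
    cmp <- compare_alleles(w$window_ref, w$snp, w$mirna, model)
    dia <- function(d) list(E_target = d$E_target,
                            E_intermediate = d$E_intermediate,
                            E_complex = d$E_complex,
                            dE_a = d$dE_a, dE_b = d$dE_b)
    report$results$thermo <<- list(
      snp_id = cmp$snp_id, ref = dia(cmp$ref), alt = dia(cmp$alt),
      delta_binding = cmp$delta_binding,
      favored_allele = cmp$favored_allele)
    writeLines(c(
      unclass(w$window_ref),
      sprintf("%s (%.2f)", cmp$ref$target_structure$dotbracket,
              cmp$ref$target_structure$energy)),
      file.path(cfg$out_dir, "ref_structure.txt"))
    state$thermo <<- cmp
    done("thermo")
  })

  if ("expr" %in% cfg$stages) run_stage("expr", function() {
    if (is.null(state$expr)) stop("expr stage needs the simulate stage")
    ex <- state$expr$expression
    grp <- group_compare(ex$log10_target, ex$genotype)
    reg <- linear_regression(ex$log10_mirna, ex$log10_target)
    report$results$expr <<- list(
      genotype_test = list(method = grp$method, statistic = grp$statistic,
                           p = grp$p),
      regression = reg[c("slope", "r_squared", "p_slope", "n")])
    done("expr")
  })

  validate_report(report)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_markdown(report), file.path(cfg$out_dir, "report.md"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[seedshift] ", ...)

write_manifest <- function(out_dir, completed, failed = NULL) {
  jsonlite::write_json(list(completed_stages = completed,
                            failed_stage = failed),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
}

assoc_report_json <- function(rep) {
  out <- lapply(rep$snps, function(res) {
    if (isTRUE(res$monomorphic))
      return(list(monomorphic = TRUE))
    flat <- function(r) list(odds_ratio = r$odds_ratio, ci_low = r$ci_low,
                             ci_high = r$ci_high, p_chisq = r$p_chisq,
                             p_fisher = r$p_fisher,
                             comparison = r$comparison_label)
    list(monomorphic = FALSE,
         hwe = list(case = res$hwe$case[c("chi2", "p", "applicable")],
                    control = res$hwe$control[c("chi2", "p", "applicable")]),
         het_or = flat(res$genotype_or$het),
         hom_or = flat(res$genotype_or$hom),
         allele_or = flat(res$allele_or))
  })
  out
}

validate_report <- function(report) {
  # structural check against the bundled JSON schema's requirements
  schema <- jsonlite::read_json(system.file("extdata", "report_schema.json",
                                            package = "seedshift"))
  for (key in unlist(schema$required))
    if (is.null(report[[key]]))
      stop("report missing required field '", key, "'", call. = FALSE)
  allowed <- unlist(schema$properties$stages_run$items$enum)
  bad <- setdiff(report$stages_run, allowed)
  if (length(bad) > 0L)
    stop("report contains unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

report_markdown <- function(report) {
  lines <- c("# seedshift pipeline report", "",
             sprintf("Seed: %d", report$seed),
             sprintf("Stages: %s", paste(report$stages_run, collapse = ", ")),
             "")
  r <- report$results
  if (!is.null(r$assoc)) {
    lines <- c(lines, "## Association", "")
    for (sid in names(r$assoc)) {
      s <- r$assoc[[sid]]
      lines <- c(lines, if (isTRUE(s$monomorphic))
        sprintf("- %s: monomorphic", sid)
        else sprintf("- %s: allele OR %.3f [%.3f, %.3f], chi-square p %.4f, Fisher p %.4f",
                     sid, s$allele_or$odds_ratio, s$allele_or$ci_low,
                     s$allele_or$ci_high, s$allele_or$p_chisq,
                     s$allele_or$p_fisher))
    }
    lines <- c(lines, "")
  }
  if (!is.null(r$scan))
    lines <- c(lines, "## Seed scan", "",
               sprintf("- effect: %s (ref %s -> alt %s)", r$scan$effect,
                       r$scan$ref_class, r$scan$alt_class), "")
  if (!is.null(r$thermo))
    lines <- c(lines, "## Thermodynamics", "",
               sprintf("- dE_b ref %.2f, alt %.2f kcal/mol; delta %.2f; favored: %s",
                       r$thermo$ref$dE_b, r$thermo$alt$dE_b,
                       r$thermo$delta_binding, r$thermo$favored_allele), "")
  if (!is.null(r$expr))
    lines <- c(lines, "## Expression", "",
               sprintf("- genotype contrast (%s): p = %.4f",
                       r$expr$genotype_test$method, r$expr$genotype_test$p),
               sprintf("- miRNA~target regression: slope %.3f, R^2 %.3f, p %.4f (n = %d)",
                       r$expr$regression$slope, r$expr$regression$r_squared,
                       r$expr$regression$p_slope, r$expr$regression$n), "")
  lines
}
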