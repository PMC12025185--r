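#' Default pipeline configuration
#'
#' Houses the numeric constants of the analysis: 1.4 Angstrom water
#' probe, 960 quadrature points per atom, 20% relative-SASA exposure
#' threshold, 4.0 Angstrom salt-bridge cutoff, and the 0.1/1.0 LysRe
#' reactivity class boundaries, together with the modifying-agent table.
#'
#' @param ... named overrides of individual entries.
#' @return a validated config list.
#' @export
default_config <- function(...) {
  cfg <- list(probe_radius = 1.4, n_points = 960L,
              exposure_threshold = 0.20, salt_bridge_cutoff = 4.0,
              reactivity_thresholds = c(0.1, 1.0),
              agents = default_agents(),
              element_radii = default_element_radii(),
              max_asa = max_asa_reference(), seed = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$probe_radius > 0, cfg$n_points >= 92,
            cfg$exposure_threshold > 0, cfg$salt_bridge_cutoff > 0,
            length(cfg$reactivity_thresholds) == 2L,
            cfg$reactivity_thresholds[1] < cfg$reactivity_thresholds[2],
            all(cfg$element_radii > 0))
  invisible(cfg)
}

# config without the bulky tables, for embedding in report JSON
.config_provenance <- function(cfg) {
  cfg$agents <- NULL
  cfg$max_asa <- NULL
  cfg
}

#' Full structure-side profiling run
#'
#' Parse -> SASA -> exposure -> surface partition -> salt bridges ->
#' reactivity at the modification pH -> triage -> crosslink pairs. When
#' `out_dir` is given, writes `triage.tsv`, `crosslink_pairs.tsv` and a
#' `profile.json` summary embedding the resolved configuration.
#'
#' @param structure_path path to a PDB file.
#' @param pka_path optional path to a pKa TSV; when absent, lysines are
#'   ranked by exposure only.
#' @param agent name of a modifying agent in the config agent table
#'   (used to resolve the modification pH).
#' @param ph explicit modification pH; overrides the agent's pH. One of
#'   `agent`/`ph` is required: the triage pH is never guessed.
#' @param config pipeline configuration, see [default_config()].
#' @param out_dir optional output directory (created if needed).
#' @return (invisibly) list with structure, sasa, exposure, partition,
#'   bridges, triage, crosslinks, ph, config.
#' @export
run_profile <- function(structure_path, pka_path = NULL, agent = NULL,
                        ph = NULL, config = default_config(),
                        out_dir = NULL) {
  validate_config(config)
  if (is.null(ph)) {
    if (is.null(agent)) stop("a modification pH is required: give ",
                             "`ph` or an `agent` with a known pH")
    hit <- match(agent, config$agents$agent)
    if (is.na(hit)) stop("unknown agent: ", agent)
    ph <- config$agents$ph[hit]
  }
  st <- parse_pdb(structure_path, radii = config$element_radii)
  sasa <- shrake_rupley(st, config$probe_radius, config$n_points)
  expo <- residue_exposure(sasa, st, config$max_asa,
                           config$exposure_threshold)
  part <- surface_partition(sasa, st)
  bridges <- detect_salt_bridges(st, config$salt_bridge_cutoff)
  pka <- if (!is.null(pka_path)) read_pka_table(pka_path) else NULL
  lys_keys <- expo$key[expo$resname == "LYS"]
  if (!is.null(pka)) {
    missing_pka <- setdiff(lys_keys,
                           pka$key[pka$resname == "LYS"])
    if (length(missing_pka) > 0L) {
      warning("no pKa entry for lysine(s): ",
              paste(missing_pka, collapse = ", "),
              "; ranked by exposure only")
    }
  }
  triage <- triage_sites(expo, bridges, ph = ph, pka_table = pka,
                         thresholds = config$reactivity_thresholds)
  pairs <- crosslink_pairs(st, config$agents)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(triage, file.path(out_dir, "triage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pairs, file.path(out_dir, "crosslink_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
      config = .config_provenance(config), ph = ph,
      total_sasa = sasa$total,
      hydrophobic_area = part$hydrophobic_area,
      hydrophilic_area = part$hydrophilic_area,
      ratio_hydrophilic_to_hydrophobic =
        part$ratio_hydrophilic_to_hydrophobic,
      n_lysines = length(lys_keys),
      n_exposed_lysines = sum(triage$exposure_class == "exposed"),
      n_candidates = sum(triage$candidate),
      candidates = triage$key[triage$candidate],
      salt_bridges = bridges)
    jsonlite::write_json(summary, file.path(out_dir, "profile.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(list(structure = st, sasa = sasa, exposure = expo,
                 partition = part, bridges = bridges, triage = triage,
                 crosslinks = pairs, ph = ph, config = config))
}

#' Thermal-stability kinetics over a long-format assay file
#'
#' Reads a tab-separated long table (columns: variant, time_min,
#' activity), fits the first-order inactivation model per variant, and
#' reports kd, half-life, fit diagnostics and the stabilization ratio R
#' against `control_label`. Variants with fewer than two positive
#' readings are flagged (`NA` fit) and the run continues. Output carries
#' both raw and 1-decimal rounded kd/t_half/R columns.
#'
#' @param assay_path path to the long-format TSV.
#' @param control_label variant label of the unmodified control.
#' @param config pipeline configuration (recorded in the JSON report).
#' @param out_dir optional output directory for `stability.tsv` and
#'   `stability.json`.
#' @return data.frame: variant, kd, t_half, r_squared, n_used, R,
#'   t_half_round, R_round, flagged.
#' @export
run_stability <- function(assay_path, control_label,
                          config = default_config(), out_dir = NULL) {
  df <- read.delim(assay_path, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need long-format TSV: variant, time, activity")
  names(df)[1:3] <- c("variant", "time", "activity")
  if (!control_label %in% df$variant) {
    stop("control label not present in assay file: ", control_label)
  }
  variants <- unique(df$variant)
  fit_one <- function(v) {
    sub <- df[df$variant == v, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    if (sum(sub$activity > 0) < 2L) return(NULL)
    suppressWarnings(
      fit_inactivation(list(times = sub$time,
                            activities = sub$activity)))
  }
  fits <- lapply(variants, fit_one)
  names(fits) <- variants
  ctrl <- fits[[control_label]]
  if (is.null(ctrl) || ctrl$no_decay) {
    stop("control series cannot be fitted with a positive decay constant")
  }
  rows <- lapply(variants, function(v) {
    f <- fits[[v]]
    if (is.null(f)) {
      return(data.frame(variant = v, kd = NA_real_, t_half = NA_real_,
                        r_squared = NA_real_, n_used = NA_integer_,
                        R = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    R <- if (v == control_label) NA_real_
         else if (f$no_decay) Inf
         else stability_ratio(f$kd, ctrl$kd)$R
    data.frame(variant = v, kd = f$kd, t_half = f$t_half,
               r_squared = f$r_squared, n_used = f$n_used, R = R,
               flagged = f$no_decay, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$t_half_round <- round(out$t_half, 1)
  out$R_round <- round(out$R, 1)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(out_dir, "stability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(config = .config_provenance(config),
                              control = control_label, results = out),
                         file.path(out_dir, "stability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `profile --structure FILE [--pka FILE] [--agent NAME]
#' [--ph X] [--out DIR]`; `stability --assay FILE --control LABEL
#' [--out DIR]`; `dm --sample X --control Y`; `simulate --n N [--seed S]
#' --out DIR` (writes a random synthetic PDB plus its ground-truth
#' annotations). Returns an exit status instead of quitting, so the
#' dispatcher is testable in-process.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the actual command line).
#' @return integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: laccmod <profile|stability|dm|simulate> [options]"
  if (length(args) == 0L) {
    message(usage)
    return(1L)
  }
  cmd <- args[1]
  rest <- args[-1]
  opt <- .parse_cli_opts(rest)
  status <- tryCatch({
    switch(cmd,
      profile = {
        if (is.null(opt$structure)) stop("--structure is required")
        res <- run_profile(opt$structure, pka_path = opt$pka,
                           agent = opt$agent,
                           ph = if (!is.null(opt$ph))
                             as.numeric(opt$ph) else NULL,
                           out_dir = if (is.null(opt$out)) "." else
                             opt$out)
        message(sprintf("profiled %d lysines; %d candidate(s)",
                        nrow(res$triage), sum(res$triage$candidate)))
        0L
      },
      stability = {
        if (is.null(opt$assay) || is.null(opt$control)) {
          stop("--assay and --control are required")
        }
        res <- run_stability(opt$assay, opt$control,
                             out_dir = if (is.null(opt$out)) "." else
                               opt$out)
        message(sprintf("fitted %d variant(s)", nrow(res)))
        0L
      },
      dm = {
        if (is.null(opt$sample) || is.null(opt$control)) {
          stop("--sample and --control are required")
        }
        r <- degree_of_modification(as.numeric(opt$sample),
                                    as.numeric(opt$control))
        cat(sprintf("DM%% = %.2f\n", r$dm_percent))
        0L
      },
      simulate = {
        n <- if (is.null(opt$n)) 20L else as.integer(opt$n)
        seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
        out_dir <- if (is.null(opt$out)) "." else opt$out
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        sim <- random_structure(n, seed = seed)
        write_pdb(sim$structure,
                  file.path(out_dir, "synthetic_structure.pdb"))
        jsonlite::write_json(sim$annotations,
                             file.path(out_dir, "annotations.json"),
                             auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        message("wrote synthetic_structure.pdb and annotations.json")
        0L
      },
      {
        message(usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

# minimal --key value parser (avoids a hard optparse dependency)
.parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !grepl("^--", args[i + 1L])) {
        opt[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opt[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      stop("unexpected argument: ", a)
    }
  }
  opt
}
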