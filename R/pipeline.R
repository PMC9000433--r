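#' Assemble and validate a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated list that can be
#' serialized to JSON and replayed. Unknown keys are rejected so a typo in a
#' config file fails loudly instead of silently using a default.
#'
#' Defaults: peak picking at signal-to-noise 4 (protein) and 10
#' (small-molecule) with a 10-point half window; replicate and binning
#' tolerances of 2.0 Da in the protein region and 0.2 Da in the
#' small-molecule region (linear-mode TOF mass accuracy is far poorer above
#' 2 kDa); peaks kept when present in at least 2 of 3 replicates; cosine
#' distance with average (UPGMA) linkage; a 75% capture threshold; no
#' matrix-blank subtraction.
#'
#' @param input_dir directory of delimited peak tables named
#'   `<isolate>_<replicate>.<ext>` (see `pattern`).
#' @param input_mzml an mzML file of centroided spectra (alternative to
#'   `input_dir`).
#' @param pattern naming pattern for spectrum/file ids.
#' @param out_dir output directory for all artifacts; `NULL` keeps results
#'   in memory only.
#' @param snr_min_protein,snr_min_np,halfwindow peak-picking settings
#'   (profile input only).
#' @param min_presence replicate-consensus retention fraction.
#' @param tol_rep_protein,tol_rep_np replicate matching tolerances (Da).
#' @param tol_bin_protein,tol_bin_np feature binning tolerances (Da).
#' @param blank_paths optional character vector of matrix-blank peak tables;
#'   `NULL` disables blank subtraction.
#' @param blank_tol blank matching tolerance (Da).
#' @param metric,linkage protein-fingerprint distance and linkage.
#' @param cut_mode,cut_value dendrogram cut (`"height"` or `"k"`, with its
#'   value); the cut is a deliberate user choice, never auto-selected.
#' @param threshold greedy capture threshold in (0, 1].
#' @param min_per_group select one representative even from groups with no
#'   small-molecule features (0 or 1).
#' @param seed integer seed recorded in the manifest.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(input_dir = NULL, input_mzml = NULL,
                       pattern = "{isolate}_{replicate}", out_dir = NULL,
                       snr_min_protein = 4, snr_min_np = 10,
                       halfwindow = 10L, min_presence = 2 / 3,
                       tol_rep_protein = 2.0, tol_rep_np = 0.2,
                       tol_bin_protein = 2.0, tol_bin_np = 0.2,
                       blank_paths = NULL, blank_tol = 0.2,
                       metric = "cosine", linkage = "average",
                       cut_mode = "k", cut_value = NULL,
                       threshold = 0.75, min_per_group = 0L, seed = 1L) {
  cfg <- list(input_dir = input_dir, input_mzml = input_mzml,
              pattern = pattern, out_dir = out_dir,
              snr_min_protein = snr_min_protein, snr_min_np = snr_min_np,
              halfwindow = as.integer(halfwindow),
              min_presence = min_presence,
              tol_rep_protein = tol_rep_protein, tol_rep_np = tol_rep_np,
              tol_bin_protein = tol_bin_protein, tol_bin_np = tol_bin_np,
              blank_paths = blank_paths, blank_tol = blank_tol,
              metric = metric, linkage = linkage,
              cut_mode = cut_mode, cut_value = cut_value,
              threshold = threshold, min_per_group = as.integer(min_per_group),
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  stopifnot(cfg$threshold > 0, cfg$threshold <= 1,
            cfg$min_presence > 0, cfg$min_presence <= 1,
            cfg$tol_rep_protein > 0, cfg$tol_rep_np > 0,
            cfg$tol_bin_protein > 0, cfg$tol_bin_np > 0,
            cfg$blank_tol > 0,
            cfg$metric %in% c("cosine", "jaccard", "dice"),
            cfg$linkage %in% c("average", "ward", "complete"),
            cfg$cut_mode %in% c("height", "k"),
            cfg$min_per_group %in% c(0L, 1L))
  structure(cfg[known], class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path config file path.
#' @return `read_config` returns a validated `"run_config"`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$halfwindow <- as.integer(cfg$halfwindow)
  cfg$min_per_group <- as.integer(cfg$min_per_group)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
}

#' @rdname read_config
#' @param config a `"run_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# stage wrapper: abort with the failing stage named, partial outputs retained
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the whole prioritization pipeline
#'
#' Executes the stages in order: read peak lists, merge replicates into
#' per-isolate consensus lists, optionally subtract a matrix blank, split
#' into protein and small-molecule regions, bin features per region, build
#' and cut the protein dendrogram, build one metabolite association network
#' per group, run the greedy selection, and write all artifacts (Newick
#' tree, group table, feature matrices, annotated GraphML networks, JSON
#' selection report, selected-id list and a run manifest) under
#' `config$out_dir`. A rerun from the same inputs and config reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param peaklists optional list of [peaklist] objects to use directly
#'   instead of reading `config$input_dir` / `config$input_mzml`.
#' @return Invisibly, a list of class `"pipeline_result"` with elements
#'   `selection` (the [prioritize_all()] result), `assignment`,
#'   `dendrogram`, `protein_matrix`, `np_matrix`, `mans` (annotated), and
#'   `consensus`.
#' @export
run_pipeline <- function(config, peaklists = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$cut_value))
    stop("config$cut_value must be set (dendrogram cut height or k)")

  input_files <- character(0)
  if (is.null(peaklists)) {
    peaklists <- run_stage("read", {
      if (!is.null(config$input_mzml)) {
        input_files <- config$input_mzml
        read_mzml(config$input_mzml, pattern = config$pattern)
      } else if (!is.null(config$input_dir)) {
        files <- sort(list.files(config$input_dir,
                                 pattern = "\\.(csv|tsv|txt)$",
                                 full.names = TRUE))
        if (!length(files)) stop("no peak tables in ", config$input_dir)
        input_files <- files
        ids <- parse_spectrum_ids(sub("\\.[^.]+$", "", basename(files)),
                                  config$pattern)
        lapply(seq_along(files), function(i)
          read_peaklist_table(files[i], ids$isolate[i], ids$replicate[i]))
      } else stop("config must provide input_dir, input_mzml, or peaklists")
    })
  }

  consensus <- run_stage("consensus", {
    by_iso <- split(peaklists,
                    vapply(peaklists, `[[`, "", "isolate_id"))
    lapply(by_iso, function(reps) {
      # region-specific replicate tolerances: merge each region separately
      split_reps <- function(lo, hi, strict_hi) lapply(reps, function(p) {
        keep <- p$peaks$mz >= lo &
          (if (strict_hi) p$peaks$mz < hi else p$peaks$mz <= hi)
        peaklist(p$peaks$mz[keep], p$peaks$intensity[keep],
                 isolate_id = p$isolate_id, replicate_id = p$replicate_id)
      })
      lo_np <- mass_regions$np["low"]; hi_np <- mass_regions$np["high"]
      hi_prot <- mass_regions$protein["high"]
      cons_np <- merge_replicates(split_reps(lo_np, hi_np, TRUE),
                                  tol = config$tol_rep_np,
                                  min_presence = config$min_presence)
      cons_prot <- merge_replicates(split_reps(hi_np, hi_prot, FALSE),
                                    tol = config$tol_rep_protein,
                                    min_presence = config$min_presence)
      new_consensus(cons_np$isolate_id,
                    rbind(cons_np$peaks, cons_prot$peaks),
                    cons_np$n_replicates)
    })
  })

  if (!is.null(config$blank_paths)) {
    consensus <- run_stage("blank_subtraction", {
      blanks <- lapply(seq_along(config$blank_paths), function(i)
        read_peaklist_table(config$blank_paths[i], "blank",
                            paste0("r", i)))
      blank_cons <- merge_replicates(blanks, tol = config$tol_rep_np,
                                     min_presence = 1 / length(blanks))
      lapply(consensus, subtract_blank, blank = blank_cons,
             tol = config$blank_tol)
    })
  }

  regions <- run_stage("split", lapply(consensus, split_regions))
  protein_matrix <- run_stage("bin_protein",
    bin_features(lapply(regions, `[[`, "protein"),
                 tol = config$tol_bin_protein))
  np_matrix <- run_stage("bin_np",
    bin_features(lapply(regions, `[[`, "np"), tol = config$tol_bin_np))

  dendro <- run_stage("cluster",
    build_dendrogram(distance_matrix(protein_matrix, config$metric),
                     linkage = config$linkage))
  assignment <- run_stage("cut",
    cut_dendrogram(dendro, mode = config$cut_mode,
                   value = config$cut_value))

  selection <- run_stage("prioritize",
    prioritize_all(assignment, np_matrix, threshold = config$threshold,
                   min_select = config$min_per_group))

  mans <- run_stage("man", lapply(seq_len(assignment$n_groups), function(g)
    annotate_man(
      build_man(names(assignment$group_of)[assignment$group_of == g],
                np_matrix, g),
      selection$per_group[[g]])))

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(...) file.path(config$out_dir, ...)
      write_newick(dendro, p("dendrogram.nwk"))
      write_group_table(assignment, p("groups.tsv"))
      write_feature_matrix(protein_matrix, p("feature_matrix_protein.tsv"))
      write_feature_matrix(np_matrix, p("feature_matrix_np.tsv"))
      for (g in seq_along(mans))
        write_graphml(mans[[g]], p(sprintf("man_group_%03d.graphml", g)))
      write_selection_report(selection, p("selection_report.json"))
      write_selected_ids(selection, p("selected_isolates.txt"))
      manifest <- list(
        package = "strainpick",
        version = as.character(utils::packageVersion("strainpick")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        config = unclass(config),
        input_md5 = if (length(input_files))
          as.list(tools::md5sum(input_files)) else list())
      jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
    })
  }

  invisible(structure(
    list(selection = selection, assignment = assignment,
         dendrogram = dendro, protein_matrix = protein_matrix,
         np_matrix = np_matrix, mans = mans, consensus = consensus,
         config = config),
    class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$assignment)
  print(x$selection)
  invisible(x)
}
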