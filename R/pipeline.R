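## Reproducible pipeline: declarative config, scan + structural analysis,
## machine-readable report bundle.

#' Scan a multi-record FASTA file for NES matches
#'
#' @param path FASTA file.
#' @param classes,allow_overlaps see [scan_nes()].
#' @return combined match data frame over all records.
#' @export
scan_fasta <- function(path, classes = NULL, allow_overlaps = TRUE) {
  aas <- Biostrings::readAAStringSet(path)
  res <- lapply(seq_along(aas), function(i) {
    id <- strsplit(names(aas)[i], "\\s+")[[1]][1]
    scan_nes(as.character(aas[[i]]), classes = classes,
             allow_overlaps = allow_overlaps, sequence_id = id)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write NES matches as TSV or JSON
#'
#' Columns: sequence_id, class, start_1based, anchors_1based,
#' anchor_letters, amphipathic (plus the 0-based coordinates).
#'
#' @param matches data frame from [scan_nes()]/[scan_fasta()].
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(matches, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(matches, path, digits = NA, auto_unbox = FALSE,
                         dataframe = "rows")
  }
  invisible(path)
}

.CONFIG_KEYS <- c("fasta", "structures", "reference_frame", "classes",
                  "allow_overlaps", "thresholds", "seed", "out_dir")

#' Build and validate a pipeline configuration
#'
#' A declarative run configuration. Unknown keys - including unknown
#' threshold names - are rejected before any work is done.
#'
#' @param x a named list, or the path of a YAML/JSON config file.
#' @return validated config (class `nes_config`) with defaults filled in.
#' @export
nes_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE))
      yaml::read_yaml(x) else jsonlite::read_json(x, simplifyVector = TRUE)
  }
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), .CONFIG_KEYS)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  th <- nes_thresholds()
  if (!is.null(x$thresholds)) {
    bad <- setdiff(names(x$thresholds), names(th))
    if (length(bad))
      stop("config error: unknown threshold(s): ", paste(bad, collapse = ", "))
    th[names(x$thresholds)] <- x$thresholds
  }
  cfg <- list(fasta = x$fasta, structures = x$structures,
              reference_frame = x$reference_frame,
              classes = x$classes,
              allow_overlaps = if (is.null(x$allow_overlaps)) TRUE
                else isTRUE(x$allow_overlaps),
              thresholds = th,
              seed = if (is.null(x$seed)) 1L else as.integer(x$seed),
              out_dir = if (is.null(x$out_dir)) "." else x$out_dir)
  class(cfg) <- "nes_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the sequence scan and/or the structural analysis described by
#' the configuration and writes a report bundle into `out_dir`: per-input
#' JSON summaries (class call, anchor map, criteria verdict), per-residue
#' TSVs (resno, name, phi, psi, sse), the match table, and a log carrying
#' the package version, the config hash, the seed and every threshold.
#' Timestamps appear only in the log so that re-running an identical
#' configuration reproduces identical reports. Failures are isolated per
#' input: the bundle's `status` is 0 on full success, 3 when some inputs
#' failed (per-item error records retained), and config errors abort with
#' status 2 before any work.
#'
#' @param config `nes_config`, list or path (see [nes_config()]).
#' @return invisibly, a list with `status`, `outputs` (paths), `reports`,
#'   `errors`.
#' @export
run_pipeline <- function(config) {
  cfg <- tryCatch(nes_config(config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(invisible(list(status = 2L, outputs = character(),
                          reports = list(),
                          errors = conditionMessage(cfg))))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(); reports <- list(); errors <- list()
  cfg_json <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "thresholds")], cfg_json,
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(cfg$fasta)) {
    res <- tryCatch({
      m <- scan_fasta(cfg$fasta, classes = cfg$classes,
                      allow_overlaps = cfg$allow_overlaps)
      p <- file.path(cfg$out_dir, "matches.tsv")
      write_matches(m, p, "tsv")
      write_matches(m, file.path(cfg$out_dir, "matches.json"), "json")
      outputs <- c(outputs, p, file.path(cfg$out_dir, "matches.json"))
      reports$matches <- m
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors$fasta <- res
  }
  frame <- NULL
  if (!is.null(cfg$reference_frame)) {
    frame <- tryCatch(frame_from_json(cfg$reference_frame),
                      error = function(e) { errors$frame <<-
                        conditionMessage(e); NULL })
    if (!is.null(frame)) frame$thresholds <- cfg$thresholds
  }
  for (sp in cfg$structures) {
    spath <- if (is.list(sp)) sp$path else sp
    chain <- if (is.list(sp) && !is.null(sp$chain)) sp$chain else NULL
    nm <- tools::file_path_sans_ext(basename(spath))
    res <- tryCatch({
      cx <- load_complex(spath)
      pep <- if (!is.null(chain)) cx$chains[[chain]] else cx$chains[[1]]
      if (is.null(pep)) stop("chain not found in ", spath)
      cl <- classify_peptide(pep)
      rep <- list(input = spath, chain = pep$chain_id,
                  call = unclass(cl$call),
                  thresholds = cfg$thresholds, seed = cfg$seed)
      if (!is.null(frame)) {
        map <- assign_anchors(pep, frame)
        crit <- nes_criteria_report(pep, frame, turn = cl$turn, map = map)
        rep$anchor_map <- list(assignments = map$assignments,
                               occupancy = as.list(map$occupancy),
                               orientation = map$orientation)
        rep$criteria <- crit$criteria
        rep$active <- crit$active
        rep$clash <- list(clashing = crit$clash$clashing,
                          worst_overlap = crit$clash$worst_overlap)
      }
      jpath <- file.path(cfg$out_dir, paste0(nm, "_report.json"))
      jsonlite::write_json(rep, jpath, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
      tsv <- data.frame(resno = cl$dihedrals$resno,
                        name = cl$dihedrals$resname,
                        phi = cl$dihedrals$phi, psi = cl$dihedrals$psi,
                        sse = as.character(cl$sse))
      tpath <- file.path(cfg$out_dir, paste0(nm, "_residues.tsv"))
      utils::write.table(tsv, tpath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, jpath, tpath)
      reports[[nm]] <- rep
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[nm]] <- res
  }
  log_path <- file.path(cfg$out_dir, "run.log")
  writeLines(c(
    sprintf("crmnes %s", as.character(utils::packageVersion("crmnes"))),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_json))),
    sprintf("seed: %d", cfg$seed),
    sprintf("threshold %s: %s", names(cfg$thresholds),
            unlist(cfg$thresholds)),
    if (length(errors)) sprintf("error[%s]: %s", names(errors),
                                unlist(errors)) else "status: ok"),
    log_path)
  outputs <- c(outputs, cfg_json, log_path)
  status <- if (length(errors)) 3L else 0L
  invisible(list(status = status, outputs = outputs, reports = reports,
                 errors = errors))
}
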