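.CONFIG_DEFAULTS <- list(
  seed = 1L,               # master seed for every stochastic stage
  n_embryos = 3L,          # cohort size
  t_end = 33,              # recording end (hpf)
  variability = "default", # "none" or "default"
  t_compare = 30,          # lineage comparison point (hpf)
  guard = 3,               # guard window (h)
  diff_times = c(12, 16, 20, 24, 30),
  founder_dt_tol = 1.0,
  founder_mirror_eps = 0.10,
  founder_topo_min = 0.8,
  out_dir = "spiralineage-run",
  log_level = "info")

#' Pipeline configuration
#'
#' Builds a validated configuration for [runPipeline()].  Every field has
#' a documented default; unknown fields are rejected.
#'
#' @param ... overrides of the defaults (see
#'   \code{spiralineage:::.CONFIG_DEFAULTS}).
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  if (cfg$n_embryos < 2) stop("n_embryos must be at least 2")
  if (!cfg$variability %in% c("none", "default"))
    stop("variability must be 'none' or 'default'")
  if (cfg$t_compare + cfg$guard > cfg$t_end)
    stop("t_compare + guard must not exceed t_end")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full lineage-analysis pipeline
#'
#' Orchestrates simulate -> match -> differences -> consensus -> founders
#' -> report on a simulated cohort, writing all artifacts (track TSVs,
#' correspondence maps, consensus tree, founder table, metrics report and
#' the serialized configuration) into the output directory.  The returned
#' manifest lists every output with its MD5 checksum; re-running an
#' identical configuration reproduces identical checksums.
#'
#' @param config a [pipelineConfig()].
#' @return data.frame manifest (file, md5), invisibly also written as
#'   \code{manifest.tsv}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logmsg <- function(stage, ...) {
    if (config$log_level != "quiet")
      message("[", stage, "] ", ...)
  }
  outputs <- character()
  addOut <- function(f) outputs <<- c(outputs, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # serialized configuration for provenance (the output path itself is
  # not part of the provenance, so identical analyses give identical
  # artifact checksums wherever they are written)
  cfgFile <- file.path(config$out_dir, "config.json")
  cfgOut <- unclass(config)
  cfgOut$out_dir <- NULL
  jsonlite::write_json(cfgOut, cfgFile, auto_unbox = TRUE, digits = NA)
  addOut(cfgFile)

  prog <- canonicalProgram()
  vb <- if (config$variability == "none") zeroVariability()
        else variabilityModel()

  logmsg("simulate", config$n_embryos, " embryos to ", config$t_end,
         " hpf (seed ", config$seed, ")")
  cohort <- stage("simulate",
    simulateCohort(config$n_embryos, baseSeed = config$seed,
                   program = prog, variability = vb,
                   tEnd = config$t_end))
  trees <- lapply(cohort, simTree)
  for (tr in trees) {
    f <- file.path(config$out_dir, paste0(embryoId(tr), "_tracks.tsv"))
    writeTracks(tr, f)
    addOut(f)
  }

  logmsg("match", "pairwise correspondence at ", config$t_compare,
         " hpf, guard ", config$guard, " h")
  maps <- list()
  for (i in seq_along(trees)) for (j in seq_along(trees)) {
    if (i >= j) next
    m <- stage("match",
      matchLineages(trees[[i]], trees[[j]], tCompare = config$t_compare,
                    guard = config$guard))
    maps[[length(maps) + 1L]] <- m
    f <- file.path(config$out_dir,
                   paste0("map_", embryoId(trees[[i]]), "_",
                          embryoId(trees[[j]]), ".json"))
    jsonlite::write_json(
      list(schema = "spiralineage/map/1", embryo_a = m@embryoA,
           embryo_b = m@embryoB, t_compare = m@tCompare,
           guard = m@guard, pairs = m@pairs,
           unmatched_a = m@unmatchedA, unmatched_b = m@unmatchedB),
      f, auto_unbox = TRUE, digits = NA, na = "null")
    addOut(f)
  }

  logmsg("diff", "difference counts at ",
         paste(config$diff_times, collapse = ", "), " hpf")
  diffs <- stage("diff", do.call(rbind, lapply(config$diff_times,
    function(tt) {
      d <- countDifferences(trees, maps, tt)
      data.frame(t = tt, embryo = d$embryo, different = d$different,
                 total = d$total,
                 percent = attr(d, "percent"))
    })))
  f <- file.path(config$out_dir, "differences.tsv")
  utils::write.table(diffs, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  addOut(f)

  logmsg("consensus", "building the consensus tree")
  cons <- stage("consensus", buildConsensus(trees, maps))
  f <- file.path(config$out_dir, "consensus.json")
  writeConsensus(cons, f)
  addOut(f)

  logmsg("founders", "bilateral founder detection")
  fp <- stage("founders",
    detectBilateralFounders(trees[[1]],
                            dtTol = config$founder_dt_tol,
                            mirrorEps = config$founder_mirror_eps,
                            topoMin = config$founder_topo_min))
  f <- file.path(config$out_dir, "founders.tsv")
  utils::write.table(fp, f, sep = "\t", quote = FALSE, row.names = FALSE)
  addOut(f)

  logmsg("report", "lineage metrics at ", config$t_compare, " hpf")
  tr1 <- trees[[1]]
  alive <- aliveAt(tr1, config$t_compare)
  rep_ <- stage("report", data.frame(
    uid = alive,
    depth = vapply(alive, function(u)
      lineageDepth(tr1, u, config$t_compare), 0L),
    age = vapply(alive, function(u)
      cellAge(tr1, u, config$t_compare), 0),
    stringsAsFactors = FALSE))
  f <- file.path(config$out_dir, "report.tsv")
  utils::write.table(rep_, f, sep = "\t", quote = FALSE, row.names = FALSE)
  addOut(f)

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  f <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}
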