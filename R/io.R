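#' Trace-table conversion and I/O
#'
#' The on-disk exchange format for traces is a long CSV/TSV table with
#' columns `molecule_id`, `frame` (0-based) and `intensity`; time is
#' `frame * frame_dt`. These helpers convert between that table and the
#' frames-by-molecules matrix used internally, and read/write it.
#'
#' @param traces frames-by-molecules matrix (columns named by molecule id).
#' @param tab long-format data frame with `molecule_id`, `frame`,
#'   `intensity`.
#' @param path file path; `.tsv`/`.txt` extensions are written tab-separated.
#' @name trace_table
NULL

#' @rdname trace_table
#' @export
matrix_to_traces <- function(traces) {
  ids <- colnames(traces)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(traces)))
  n_frames <- nrow(traces)
  tibble::tibble(
    molecule_id = rep(ids, each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = ncol(traces)),
    intensity = as.vector(traces))
}

#' @rdname trace_table
#' @export
traces_to_matrix <- function(tab) {
  need <- c("molecule_id", "frame", "intensity")
  if (!all(need %in% names(tab))) {
    stop("trace table needs columns molecule_id, frame, intensity",
         call. = FALSE)
  }
  ids <- unique(tab$molecule_id)
  n_frames <- length(unique(tab$frame))
  m <- matrix(NA_real_, nrow = n_frames, ncol = length(ids),
              dimnames = list(NULL, as.character(ids)))
  ord <- order(match(tab$molecule_id, ids), tab$frame)
  m[] <- tab$intensity[ord]
  m
}

sep_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' @rdname trace_table
#' @export
write_trace_table <- function(traces, path) {
  if (is.matrix(traces)) traces <- matrix_to_traces(traces)
  ok <- tryCatch({
    utils::write.table(traces, path, sep = sep_for(path), row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write trace table to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname trace_table
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Write a self-contained simulated fixture to disk
#'
#' Simulates a population from `config` and writes everything a downstream
#' consumer needs: the trace table (`traces.csv`), the ground truth
#' (`truth.csv`), the configuration (`config.yaml`) and, optionally, a
#' rendered TIFF movie (`movie.tif`). All files round-trip losslessly
#' through the package readers.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param movie also render and write a synthetic image stack.
#' @param ... passed to [render_movie()] when `movie = TRUE`.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture <- function(config, dir, movie = FALSE, ...) {
  ok <- tryCatch({
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok) || !dir.exists(dir)) {
    stop("cannot create fixture directory '", dir, "'", call. = FALSE)
  }
  pop <- simulate_population(config)
  paths <- list(traces = file.path(dir, "traces.csv"),
                truth = file.path(dir, "truth.csv"),
                config = file.path(dir, "config.yaml"))
  write_trace_table(pop$intensity, paths$traces)
  utils::write.csv(pop$truth, paths$truth, row.names = FALSE)
  # 17 significant digits: doubles round-trip exactly through the YAML
  yaml::write_yaml(config_to_list(config), paths$config, precision = 17L)
  if (movie) {
    n <- ncol(pop$intensity)
    paths$movie <- file.path(dir, "movie.tif")
    pos <- grid_positions(n, image_shape = c(48L, 48L))
    stack <- render_movie(pop$intensity, pos, seed = config$seed + 1L, ...)
    # float TIFF stores [0, 1]: clamp the read-noise floor, scale by 2^16
    write_movie_tiff(pmax(stack, 0) / 2^16, paths$movie)
  }
  invisible(paths)
}

# flatten a sim_config into plain lists for YAML
config_to_list <- function(config) {
  rl <- function(r) list(k_on = r$k_on, k_off = r$k_off,
                         probe_conc = r$probe_conc)
  list(n_molecules = config$n_molecules, snv_fraction = config$snv_fraction,
       duration = config$duration, frame_rate = config$frame_rate,
       snv_rates = rl(config$snv_rates), wt_rates = rl(config$wt_rates),
       bg_rates = rl(config$bg_rates),
       noise = unclass(config$noise),
       background_rate = config$background_rate, seed = config$seed)
}

#' Rebuild a simulation configuration from a YAML/JSON file
#'
#' @param path a `config.yaml` (or `.json`) written by [write_fixture()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rs <- function(l) rate_set(l$k_on, l$k_off, l$probe_conc)
  sim_config(n_molecules = x$n_molecules, snv_fraction = x$snv_fraction,
             duration = x$duration, frame_rate = x$frame_rate,
             snv_rates = rs(x$snv_rates), wt_rates = rs(x$wt_rates),
             bg_rates = rs(x$bg_rates),
             noise = do.call(noise_model, x$noise),
             background_rate = x$background_rate, seed = x$seed)
}
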