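## Configuration files (YAML, one file per run, sections: cell, founder,
## evolution, simulation, experiment) and delimited-table output with an
## embedded metadata header, so every result file carries its fully resolved
## configuration hash and seed.

#' RunConfig: a fully resolved run configuration
#'
#' @slot cell a [CellParams].
#' @slot founder a [PlasmidGenotype].
#' @slot evolution an [EvolutionParams].
#' @slot simulation list: `cap`, `steps`, `recordEvery`, `nInit`, `seed`.
#' @slot experiment free-form list for experiment drivers.
#' @export
setClass("RunConfig",
    representation(cell = "CellParams", founder = "PlasmidGenotype",
                   evolution = "EvolutionParams", simulation = "list",
                   experiment = "list"))

setValidity("RunConfig", function(object) {
    msg <- character()
    sim <- object@simulation
    need <- c("cap", "steps", "recordEvery", "nInit", "seed")
    if (!all(need %in% names(sim)))
        msg <- c(msg, paste("simulation must name:",
                            paste(need, collapse = ", ")))
    else if (sim$cap < 1 || sim$steps < 1 || sim$recordEvery < 1)
        msg <- c(msg, "simulation: cap, steps, recordEvery must be >= 1")
    b <- object@evolution@bounds
    gt <- object@founder
    for (tr in c("alpha", "kappa", "beta"))
        if (slot(gt, tr) > b[[tr]])
            msg <- c(msg, sprintf("founder %s = %g exceeds bound %s_max = %g",
                                  tr, slot(gt, tr), tr, b[[tr]]))
    if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param cell,founder,evolution,simulation,experiment see slots; missing
#'   simulation entries are filled with defaults.
#' @export
runConfig <- function(cell = cellParams(), founder = PlasmidGenotype(),
                      evolution = evolutionParams(),
                      simulation = list(), experiment = list()) {
    defaults <- list(cap = 1000L, steps = 10000L, recordEvery = 100L,
                     nInit = 4L, seed = 1L)
    simulation <- utils::modifyList(defaults, simulation)
    new("RunConfig", cell = cell, founder = founder, evolution = evolution,
        simulation = simulation, experiment = experiment)
}

#' Serialise a RunConfig to a YAML string or file
#'
#' @param config a [RunConfig-class].
#' @param path optional file path; when NULL the YAML text is returned.
#' @return the YAML string, invisibly when written to a file.
#' @export
serializeConfig <- function(config, path = NULL) {
    stopifnot(is(config, "RunConfig"))
    p <- config@cell; gt <- config@founder; ev <- config@evolution
    x <- list(
        cell = list(g0 = p@g0, B = p@B, steepness = p@steepness, c = p@c,
                    cInh = p@cInh, M0 = p@M0, tau = p@tau, dt = p@dt),
        founder = list(alpha = gt@alpha, kappa = gt@kappa, beta = gt@beta),
        evolution = list(mu = ev@mu, step = ev@step,
                         bounds = as.list(ev@bounds),
                         free = as.list(ev@free)),
        simulation = config@simulation,
        experiment = config@experiment)
    txt <- yaml::as.yaml(x, precision = 15L)
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(txt))
    }
    txt
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `cell`, `founder`, `evolution`,
#' `simulation` and `experiment`; missing values take the package defaults
#' (the reference study conditions). Validation errors name the offending
#' field and constraint. `parse(serialize(config))` reproduces `config`.
#'
#' @param path a file path, or a YAML string containing a newline.
#' @return a validated [RunConfig-class].
#' @export
loadConfig <- function(path) {
    x <- if (grepl("\n", path)) yaml::yaml.load(path)
         else yaml::read_yaml(path)
    if (is.null(x)) x <- list()
    cellArgs <- x$cell
    badCell <- setdiff(names(cellArgs),
                       c("g0", "B", "steepness", "c", "cInh", "M0", "tau",
                         "dt"))
    if (length(badCell))
        stop("unknown cell parameter(s): ", paste(badCell, collapse = ", "))
    cell <- do.call(cellParams, as.list(cellArgs))
    fo <- x$founder
    founder <- PlasmidGenotype(alpha = fo$alpha %||% 0,
                               kappa = fo$kappa %||% 0,
                               beta = fo$beta %||% 0)
    evl <- x$evolution
    evolution <- evolutionParams(
        mu = evl$mu %||% 0.02, step = evl$step %||% 0.1,
        bounds = if (is.null(evl$bounds)) c(alpha = 2, kappa = 3, beta = 1)
                 else unlist(evl$bounds),
        free = if (is.null(evl$free))
                   c(alpha = TRUE, kappa = TRUE, beta = TRUE)
               else unlist(evl$free))
    runConfig(cell = cell, founder = founder, evolution = evolution,
              simulation = as.list(x$simulation),
              experiment = as.list(x$experiment))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of a run configuration
#'
#' Polynomial rolling hash (base 31 modulo the Mersenne prime 2^31 - 1) over
#' the serialised YAML, used to stamp output tables so results can be traced
#' back to the exact configuration that produced them.
#'
#' @param config a [RunConfig-class] (or any character scalar).
#' @return an 8-character hexadecimal string.
#' @export
configHash <- function(config) {
    txt <- if (is.character(config)) config else serializeConfig(config)
    bytes <- utf8ToInt(txt)
    h <- 17
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Write a results table with an embedded metadata header
#'
#' Writes tab-separated values preceded by a commented (`# key: value`) header
#' block recording at least the package version, creation time, configuration
#' hash and seed. Values survive a write/read round trip at full double
#' precision.
#'
#' @param records a data.frame.
#' @param path output file path.
#' @param metadata named list written into the header.
#' @return `path`, invisibly.
#' @export
writeTableWithMeta <- function(records, path, metadata = list()) {
    stopifnot(is.data.frame(records))
    metadata <- c(list(package = "plasmidCNC",
                       version = as.character(utils::packageVersion("plasmidCNC"))),
                  metadata)
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(metadata))
        writeLines(sprintf("# %s: %s", k, format(metadata[[k]], digits = 17)),
                   con)
    utils::write.table(format(records, digits = 17, trim = TRUE,
                              scientific = NA),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a table written by [writeTableWithMeta]
#'
#' @param path file path.
#' @return the data.frame, with the parsed header in attribute `metadata`.
#' @export
readTableWithMeta <- function(path) {
    lines <- readLines(path)
    isMeta <- grepl("^# ", lines)
    nMeta <- if (any(!isMeta)) which(!isMeta)[1] - 1L else length(lines)
    meta <- list()
    for (ln in lines[seq_len(nMeta)]) {
        kv <- sub("^# ", "", ln)
        key <- sub(":.*$", "", kv)
        meta[[key]] <- sub("^[^:]*: ?", "", kv)
    }
    body <- lines[-seq_len(nMeta)]
    body <- body[nzchar(trimws(body))]
    df <- if (length(body))
        utils::read.table(text = body, header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
    else data.frame()
    attr(df, "metadata") <- meta
    df
}
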