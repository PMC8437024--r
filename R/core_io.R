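# Domain types and file I/O: character matrices (NEXUS), occurrence tables
# (CSV), timescales (YAML), dated trees (newick + root-age token), and the
# analysis configuration.
#
# Conventions shared by every module: ages are Ma before present ("older" =
# numerically larger); branch durations are Myr; rates are per lineage-Myr.

# ---------------------------------------------------------------------------
# CharacterMatrix

#' Construct a discrete character matrix
#'
#' A taxa-by-characters matrix of non-negative integer states, with `NA`
#' marking cells that carry no information. Cells can additionally be flagged
#' inapplicable; inapplicable cells are treated as missing when computing
#' likelihoods (marginalized over states) but are written back to NEXUS as
#' `-` rather than `?`.
#'
#' @param states integer matrix, rows named by taxon; `NA` = missing.
#' @param inapplicable optional logical matrix of the same shape.
#' @param k_per_char optional integer vector of state counts per character;
#'   derived from the observed symbols when omitted.
#' @return an object of class `character_matrix`.
#' @export
character_matrix <- function(states, inapplicable = NULL, k_per_char = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  taxa <- rownames(states)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop("taxon labels must be present and unique")
  if (is.null(inapplicable)) {
    inapplicable <- matrix(FALSE, nrow(states), ncol(states))
  } else {
    inapplicable <- as.matrix(inapplicable)
    if (!identical(dim(inapplicable), dim(states)))
      stop("'inapplicable' must match the dimensions of 'states'")
  }
  states[inapplicable] <- NA_integer_
  observed_k <- apply(states, 2, function(x) {
    if (all(is.na(x))) 1L else max(x, na.rm = TRUE) + 1L
  })
  if (is.null(k_per_char)) {
    k_per_char <- pmax(observed_k, 1L)
  } else {
    k_per_char <- as.integer(k_per_char)
    if (length(k_per_char) != ncol(states))
      stop("'k_per_char' must have one entry per character")
    bad <- which(observed_k > k_per_char)
    if (length(bad))
      stop("observed states exceed k_per_char for character(s) ",
           paste(bad, collapse = ", "))
  }
  if (any(!is.na(states) & states < 0L))
    stop("states must be non-negative integers")
  structure(list(states = states, inapplicable = inapplicable,
                 k_per_char = as.integer(k_per_char), taxa = taxa),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%d missing cells)\n",
              nrow(x$states), ncol(x$states), sum(is.na(x$states))))
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$states)

#' Read a morphological character matrix from a NEXUS file
#'
#' Accepts a CHARACTERS or DATA block with digit state symbols, `?` for
#' missing and `-` for inapplicable. Declared NTAX/NCHAR dimensions are
#' checked against the parsed matrix.
#'
#' @param path path to a NEXUS file.
#' @return a [character_matrix()].
#' @export
read_character_matrix <- function(path) {
  raw <- tryCatch(ape::read.nexus.data(path), error = function(e)
    stop("NEXUS parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  lines <- readLines(path, warn = FALSE)
  dimline <- grep("dimensions", lines, ignore.case = TRUE, value = TRUE)
  ntax <- nchar_decl <- NA_integer_
  if (length(dimline)) {
    m <- regmatches(dimline[1],
                    regexec("ntax\\s*=\\s*([0-9]+)", dimline[1], ignore.case = TRUE))[[1]]
    if (length(m) == 2) ntax <- as.integer(m[2])
    m <- regmatches(dimline[1],
                    regexec("nchar\\s*=\\s*([0-9]+)", dimline[1], ignore.case = TRUE))[[1]]
    if (length(m) == 2) nchar_decl <- as.integer(m[2])
  }
  taxa <- names(raw)
  nc <- unique(lengths(raw))
  if (length(nc) != 1)
    stop("NEXUS parse error in '", path, "': rows of unequal length")
  if (!is.na(ntax) && ntax != length(taxa))
    stop("declared NTAX=", ntax, " but matrix has ", length(taxa), " taxa")
  if (!is.na(nchar_decl) && nchar_decl != nc)
    stop("declared NCHAR=", nchar_decl, " but matrix has ", nc, " characters")
  states <- matrix(NA_integer_, length(taxa), nc, dimnames = list(taxa, NULL))
  inapp <- matrix(FALSE, length(taxa), nc)
  for (i in seq_along(raw)) {
    sym <- raw[[i]]
    bad <- !(sym %in% c(as.character(0:9), "?", "-"))
    if (any(bad))
      stop("state symbol '", sym[which(bad)[1]], "' outside the declared ",
           "symbol set for taxon '", taxa[i], "'")
    inapp[i, ] <- sym == "-"
    keep <- !(sym %in% c("?", "-"))
    states[i, keep] <- as.integer(sym[keep])
  }
  character_matrix(states, inapplicable = inapp)
}

#' Write a character matrix to NEXUS
#'
#' @param cm a [character_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(cm, path) {
  st <- cm$states
  sym <- matrix("?", nrow(st), ncol(st))
  sym[!is.na(st)] <- as.character(st[!is.na(st)])
  sym[cm$inapplicable] <- "-"
  rows <- apply(sym, 1, paste0, collapse = "")
  pad <- max(nchar(cm$taxa)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
    "  MATRIX"
  ), con)
  writeLines(sprintf("    %-*s%s", pad, cm$taxa, rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# OccurrenceTable

#' Construct a fossil-occurrence table
#'
#' One row per species-level occurrence: species and genus labels, the id of
#' the collection it comes from, and older/younger age bounds in Ma.
#'
#' @param species,genus character vectors.
#' @param collection collection ids (shared across co-occurring taxa).
#' @param max_ma,min_ma older and younger age bounds (Ma).
#' @return a data frame of class `occurrence_table`.
#' @export
occurrence_table <- function(species, genus, collection, max_ma, min_ma) {
  df <- data.frame(species = as.character(species),
                   genus = as.character(genus),
                   collection = as.character(collection),
                   max_ma = as.numeric(max_ma), min_ma = as.numeric(min_ma),
                   stringsAsFactors = FALSE)
  bad <- which(df$max_ma < df$min_ma | !is.finite(df$max_ma) | !is.finite(df$min_ma))
  if (length(bad))
    stop("occurrence rows with max_ma < min_ma or non-finite ages: ",
         paste(utils::head(bad, 10), collapse = ", "))
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read an occurrence table from CSV
#'
#' Requires columns `species`, `genus`, `collection`, `max_ma`, `min_ma`.
#'
#' @param path path to a comma-separated UTF-8 file with a header row.
#' @return an [occurrence_table()].
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "genus", "collection", "max_ma", "min_ma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence CSV is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("max_ma", "min_ma")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric '", col, "' in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    df[[col]] <- v
  }
  occurrence_table(df$species, df$genus, df$collection, df$max_ma, df$min_ma)
}

#' Write an occurrence table to CSV
#' @param occ an [occurrence_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Timescale

#' Construct a geological timescale of contiguous intervals
#'
#' Intervals are ordered from oldest to youngest; each interval's younger
#' bound must equal the next interval's older bound.
#'
#' @param name interval names.
#' @param older,younger bounds in Ma.
#' @return a data frame of class `timescale`.
#' @export
timescale <- function(name, older, younger) {
  df <- data.frame(name = as.character(name), older = as.numeric(older),
                   younger = as.numeric(younger), stringsAsFactors = FALSE)
  if (any(df$older <= df$younger))
    stop("each interval's older bound must exceed its younger bound")
  if (nrow(df) > 1) {
    gap <- abs(df$older[-1] - df$younger[-nrow(df)])
    if (any(gap > 1e-9))
      stop("intervals must be contiguous and ordered old to young")
  }
  class(df) <- c("timescale", "data.frame")
  df
}

#' Cambrian-Ordovician stage timescale, optionally split into stage-slices
#'
#' Stage boundaries follow the current international chronostratigraphic
#' chart, spanning Cambrian Stage 3 (521 Ma) through the Hirnantian
#' (443.8 Ma). Collections are assigned to these bins (or equal subdivisions
#' of them) when estimating skyline rates.
#'
#' @param slices_per_stage number of equal slices each stage is cut into.
#' @return a [timescale()].
#' @export
ordovician_timescale <- function(slices_per_stage = 1L) {
  stages <- data.frame(
    name = c("Cm Stage 3", "Cm Stage 4", "Wuliuan", "Drumian", "Guzhangian",
             "Paibian", "Jiangshanian", "Cm Stage 10", "Tremadocian", "Floian",
             "Dapingian", "Darriwilian", "Sandbian", "Katian", "Hirnantian"),
    older = c(521, 514.5, 509, 504.5, 500.5, 497, 494, 489.5, 486.85,
              477.08, 471.26, 469.42, 458.18, 453.0, 445.2),
    younger = c(514.5, 509, 504.5, 500.5, 497, 494, 489.5, 486.85, 477.08,
                471.26, 469.42, 458.18, 453.0, 445.2, 443.8))
  s <- as.integer(slices_per_stage)
  if (s < 1L) stop("slices_per_stage must be >= 1")
  if (s == 1L) return(timescale(stages$name, stages$older, stages$younger))
  nm <- ol <- yg <- NULL
  for (i in seq_len(nrow(stages))) {
    b <- seq(stages$older[i], stages$younger[i], length.out = s + 1)
    nm <- c(nm, paste0(stages$name[i], " s", seq_len(s)))
    ol <- c(ol, b[-(s + 1)])
    yg <- c(yg, b[-1])
  }
  timescale(nm, ol, yg)
}

#' Read / write a timescale as YAML
#' @param path YAML file with a top-level `intervals` list of
#'   `name`/`older`/`younger` entries.
#' @return a [timescale()].
#' @export
read_timescale <- function(path) {
  y <- yaml::read_yaml(path)
  iv <- y$intervals %||% y
  timescale(vapply(iv, function(i) as.character(i$name), ""),
            vapply(iv, function(i) as.numeric(i$older), 0),
            vapply(iv, function(i) as.numeric(i$younger), 0))
}

#' @rdname read_timescale
#' @param ts a [timescale()].
#' @export
write_timescale <- function(ts, path) {
  iv <- lapply(seq_len(nrow(ts)), function(i)
    list(name = ts$name[i], older = ts$older[i], younger = ts$younger[i]))
  yaml::write_yaml(list(intervals = iv), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Dated trees

#' Node ages of a dated tree
#'
#' A dated tree is an `ape::phylo` with branch lengths in Myr and a
#' `root.time` element giving the root age in Ma (the `paleotree`
#' convention). Ages decrease toward the present.
#'
#' @param tree a dated `phylo`.
#' @return numeric vector of ages (Ma), indexed by node number.
#' @export
node_ages <- function(tree) {
  if (is.null(tree$root.time)) stop("tree has no root.time; not dated")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths; undated node present")
  depths <- ape::node.depth.edgelength(tree)
  tree$root.time - depths
}

#' Rebuild branch lengths of a tree from a vector of node ages
#'
#' @param tree a `phylo` (topology used as-is).
#' @param ages ages in Ma indexed by node number (tips first, `ape` order).
#' @return a dated `phylo` with `root.time` set.
#' @export
tree_from_ages <- function(tree, ages) {
  root <- ape::Ntip(tree) + 1L
  el <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(el < -1e-9))
    stop("node older than its parent: invalid age vector")
  tree$edge.length <- pmax(el, 0)
  tree$root.time <- unname(ages[root])
  tree
}

#' Write a dated tree to newick with a root-age token
#'
#' The file holds a `[&root_age=...]` comment followed by the newick string;
#' branch lengths are Myr, so re-reading recovers all node ages.
#'
#' @param tree a dated `phylo` (with `root.time`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(tree, path) {
  if (is.null(tree$root.time)) stop("tree has no root.time; undated")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all" else
      paste(tree$edge[is.na(tree$edge.length), 2], collapse = ", ")
    stop("undated node(s): ", bad)
  }
  nwk <- ape::write.tree(tree, digits = 15)
  writeLines(paste0("[&root_age=", format(tree$root.time, digits = 17), "]", nwk),
             path)
  invisible(path)
}

#' Read a dated tree written by [write_dated_tree()]
#' @param path newick file with a root-age token.
#' @return a dated `phylo`.
#' @export
read_dated_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  m <- regexec("^\\[&root_age=([0-9.eE+-]+)\\]", txt)[[1]]
  if (m[1] == -1) stop("no [&root_age=...] token in '", path, "'")
  root_age <- as.numeric(regmatches(txt, regexec(
    "^\\[&root_age=([0-9.eE+-]+)\\]", txt))[[1]][2])
  nwk <- sub("^\\[&root_age=[0-9.eE+-]+\\]", "", txt)
  tree <- ape::read.tree(text = nwk)
  tree$root.time <- root_age
  tree
}

# ---------------------------------------------------------------------------
# AnalysisConfig

#' Analysis configuration
#'
#' Bundles the knobs of the dating analysis: the basal-divergence scan
#' window and grid step (Ma), the early-burst breakpoint tau (Ma), the
#' number of first-appearance replicates, the master seed, the optional
#' ascertainment correction, the number of discretized lognormal rate
#' classes, and the among-character lognormal scale sigma (estimated from
#' parsimony change counts when `NULL`).
#'
#' @param scan_min,scan_max basal-age scan bounds in Ma (young, old).
#' @param grid_step scan grid step in Myr.
#' @param tau early-burst breakpoint in Ma.
#' @param replicates number of FA replicates.
#' @param seed master random seed.
#' @param ascertainment apply a variable-characters-only correction?
#' @param n_rate_classes number of among-character rate classes.
#' @param sigma among-character lognormal scale, or `NULL` to estimate.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(scan_min = 466, scan_max = 521, grid_step = 1,
                            tau = 462, replicates = 100, seed = 1,
                            ascertainment = FALSE, n_rate_classes = 4L,
                            sigma = NULL) {
  if (scan_min >= scan_max) stop("scan bounds must satisfy scan_min < scan_max")
  if (grid_step <= 0) stop("grid step must be > 0")
  if (replicates < 1) stop("replicate count must be >= 1")
  structure(list(scan_min = scan_min, scan_max = scan_max,
                 grid_step = grid_step, tau = tau,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 ascertainment = isTRUE(ascertainment),
                 n_rate_classes = as.integer(n_rate_classes), sigma = sigma),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y[intersect(names(y), names(formals(analysis_config)))])
}

#' @rdname read_config
#' @param cfg an [analysis_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
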