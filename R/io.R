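# Network and dataset input/output.
#
# Two network formats are supported:
#  * a BIF subset: `network`, `variable` (discrete) and `probability`
#    blocks; state labels are written as the integer codes 0..r-1;
#  * a plain two-file format: an arc list ("parent<TAB>child", one arc per
#    line, preceded by one "node<TAB>arity" declaration line per node
#    marked with "#node"), plus an optional CPT file keyed by variable and
#    parent configuration.

#' Read a Bayesian network from file
#'
#' @param path file path.  `.bif` files are parsed as BIF; anything else
#'   as the plain arc-list format (with CPTs taken from
#'   `paste0(path, ".cpt")` when that file exists, or from `cpt_path`).
#' @param cpt_path optional path of the CPT file for the plain format.
#' @return a `discrete_bn`, or a bare `bn_dag` if a plain file carries no
#'   CPTs.
#' @export
read_network <- function(path, cpt_path = NULL) {
  if (grepl("\\.bif$", path, ignore.case = TRUE)) read_bif(path)
  else read_plain_network(path, cpt_path)
}

#' Write a Bayesian network to file
#'
#' @param bn a `discrete_bn` (or a `bn_dag`, plain format only).
#' @param path output path; `.bif` selects BIF, anything else the plain
#'   format (CPTs go to `paste0(path, ".cpt")`).
#' @return `path`, invisibly.
#' @export
write_network <- function(bn, path) {
  if (grepl("\\.bif$", path, ignore.case = TRUE)) write_bif(bn, path)
  else write_plain_network(bn, path)
  invisible(path)
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

read_bif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- character(0)
  arities <- integer(0)
  cpts <- list()
  parent_list <- list()
  i <- 1L
  nl <- length(lines)
  skip_blank <- function(i) {
    while (i <= nl && grepl("^\\s*(//.*)?$", lines[i])) i <- i + 1L
    i
  }
  while ({i <- skip_blank(i); i <= nl}) {
    ln <- lines[i]
    if (grepl("^\\s*network", ln)) {
      while (i <= nl && !grepl("\\}", lines[i])) i <- i + 1L
      i <- i + 1L
    } else if (grepl("^\\s*variable\\s+", ln)) {
      name <- sub("^\\s*variable\\s+([^[:space:]{]+).*$", "\\1", ln)
      j <- i
      ar <- NA_integer_
      repeat {
        m <- regmatches(lines[j],
                        regexec("type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]", lines[j]))[[1]]
        if (length(m) == 2L) ar <- as.integer(m[2])
        if (grepl("\\}\\s*$", lines[j]) && j > i || j >= nl) break
        j <- j + 1L
      }
      if (is.na(ar)) parse_error(path, i, paste0("variable ", name, " has no discrete type"))
      if (ar < 2L) parse_error(path, i, paste0("variable ", name, " must have arity >= 2"))
      nodes <- c(nodes, name)
      arities[name] <- ar
      i <- j + 1L
    } else if (grepl("^\\s*probability\\s*\\(", ln)) {
      hdr <- regmatches(ln, regexec("probability\\s*\\(\\s*([^)|]+?)\\s*(\\|\\s*([^)]*))?\\)", ln))[[1]]
      if (length(hdr) == 0L) parse_error(path, i, "malformed probability header")
      child <- trimws(hdr[2])
      pars <- trimws(strsplit(hdr[4], ",")[[1]])
      pars <- pars[nzchar(pars)]
      if (!(child %in% nodes)) parse_error(path, i, paste0("unknown variable ", child))
      if (any(!(pars %in% nodes))) parse_error(path, i, "unknown parent variable")
      q <- prod(arities[pars])
      cpt <- matrix(NA_real_, q, arities[child])
      j <- i + 1L
      while (j <= nl && !grepl("^\\s*\\}", lines[j])) {
        row <- lines[j]
        if (grepl("^\\s*table", row)) {
          vals <- suppressWarnings(as.numeric(strsplit(
            gsub("[;]", "", sub("^\\s*table\\s*", "", row)), ",")[[1]]))
          if (length(vals) != arities[child] || anyNA(vals))
            parse_error(path, j, "bad table row")
          cpt[1L, ] <- vals
        } else if (grepl("^\\s*\\(", row)) {
          m <- regmatches(row, regexec("^\\s*\\(([^)]*)\\)\\s*(.*?);?\\s*$", row))[[1]]
          if (length(m) == 0L) parse_error(path, j, "bad probability row")
          conf <- suppressWarnings(as.integer(trimws(strsplit(m[2], ",")[[1]])))
          vals <- suppressWarnings(as.numeric(strsplit(m[3], ",")[[1]]))
          if (anyNA(conf) || length(conf) != length(pars))
            parse_error(path, j, "bad parent configuration")
          if (length(vals) != arities[child] || anyNA(vals))
            parse_error(path, j, "bad probability vector")
          cpt[config_index(matrix(conf, nrow = 1L), arities[pars]), ] <- vals
        } else if (!grepl("^\\s*$", row)) {
          parse_error(path, j, "unrecognized line in probability block")
        }
        j <- j + 1L
      }
      if (anyNA(cpt)) parse_error(path, i, paste0("incomplete CPT for ", child))
      if (any(abs(rowSums(cpt) - 1) > 1e-6))
        parse_error(path, i, paste0("CPT row for ", child, " does not sum to 1"))
      cpts[[child]] <- cpt
      parent_list[[child]] <- pars
      i <- j + 1L
    } else {
      parse_error(path, i, "unrecognized top-level construct")
    }
  }
  arcs <- do.call(rbind, lapply(names(parent_list), function(ch) {
    ps <- parent_list[[ch]]
    if (length(ps)) cbind(ps, ch) else NULL
  }))
  g <- dag(nodes, arcs)
  # reorder CPT rows: file parents may differ in order from node order
  for (ch in names(parent_list)) {
    ps_file <- parent_list[[ch]]
    ps_canon <- parents(g, ch)
    if (!identical(ps_file, ps_canon) && length(ps_file) > 0L) {
      confs <- all_configs(arities[ps_canon])
      rows <- config_index(confs[, match(ps_file, ps_canon), drop = FALSE],
                           arities[ps_file])
      cpts[[ch]] <- cpts[[ch]][rows, , drop = FALSE]
    }
  }
  discrete_bn(g, arities, cpts)
}

# all parent configurations in canonical (mixed-radix) row order
all_configs <- function(pars_arity) {
  if (length(pars_arity) == 0L)
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  g <- expand.grid(rev(lapply(pars_arity, function(r) 0:(r - 1L))),
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_along(pars_arity)), drop = FALSE])
}

write_bif <- function(bn, path) {
  if (!inherits(bn, "discrete_bn"))
    stop("BIF output requires a parameterized network (discrete_bn)")
  g <- bn$structure
  out <- c("network unknown {", "}")
  for (v in g$nodes) {
    r <- bn$arities[[v]]
    out <- c(out,
             sprintf("variable %s {", v),
             sprintf("  type discrete [ %d ] { %s };", r,
                     paste(0:(r - 1L), collapse = ", ")),
             "}")
  }
  for (v in g$nodes) {
    ps <- parents(g, v)
    cpt <- bn$cpts[[v]]
    if (length(ps) == 0L) {
      out <- c(out,
               sprintf("probability ( %s ) {", v),
               sprintf("  table %s;", paste(format(cpt[1L, ], digits = 17),
                                            collapse = ", ")),
               "}")
    } else {
      confs <- all_configs(bn$arities[ps])
      rows <- vapply(seq_len(nrow(cpt)), function(r)
        sprintf("  (%s) %s;", paste(confs[r, ], collapse = ", "),
                paste(format(cpt[r, ], digits = 17), collapse = ", ")),
        character(1))
      out <- c(out,
               sprintf("probability ( %s | %s ) {", v, paste(ps, collapse = ", ")),
               rows, "}")
    }
  }
  writeLines(out, path)
}

read_plain_network <- function(path, cpt_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  nodes <- character(0); arities <- integer(0)
  from <- character(0); to <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#node")) {
      f <- strsplit(sub("^#node\\s+", "", ln), "\\s+")[[1]]
      if (length(f) != 2L) parse_error(path, i, "node line must be '#node name arity'")
      nodes <- c(nodes, f[1]); arities[f[1]] <- as.integer(f[2])
    } else if (startsWith(ln, "#")) {
      next
    } else {
      f <- strsplit(ln, "\t")[[1]]
      if (length(f) != 2L) parse_error(path, i, "arc line must be 'parent<TAB>child'")
      from <- c(from, f[1]); to <- c(to, f[2])
    }
  }
  if (length(nodes) == 0L) {
    nodes <- unique(c(from, to))
    arities <- rep(2L, length(nodes)); names(arities) <- nodes
  }
  g <- dag(nodes, if (length(from)) cbind(from, to) else NULL)
  if (is.null(cpt_path) && file.exists(paste0(path, ".cpt")))
    cpt_path <- paste0(path, ".cpt")
  if (is.null(cpt_path)) return(g)
  cpts <- read_plain_cpts(cpt_path, g, arities)
  discrete_bn(g, arities, cpts)
}

# CPT file: one line per row, "variable<TAB>config<TAB>p0,p1,..." where
# config is the comma-separated parent states ("." for root nodes).
read_plain_cpts <- function(path, g, arities) {
  lines <- readLines(path, warn = FALSE)
  cpts <- lapply(g$nodes, function(v)
    matrix(NA_real_, prod(arities[parents(g, v)]), arities[[v]]))
  names(cpts) <- g$nodes
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 3L) parse_error(path, i, "CPT line must have 3 tab-separated fields")
    v <- f[1]
    if (!(v %in% g$nodes)) parse_error(path, i, paste0("unknown variable ", v))
    ps <- parents(g, v)
    conf <- if (f[2] == ".") integer(0) else
      suppressWarnings(as.integer(strsplit(f[2], ",")[[1]]))
    if (length(conf) != length(ps) || anyNA(conf))
      parse_error(path, i, "bad parent configuration")
    vals <- suppressWarnings(as.numeric(strsplit(f[3], ",")[[1]]))
    if (length(vals) != arities[[v]] || anyNA(vals))
      parse_error(path, i, "bad probability vector")
    if (abs(sum(vals) - 1) > 1e-6)
      parse_error(path, i, "probability row does not sum to 1")
    cpts[[v]][config_index(matrix(conf, nrow = 1L), arities[ps]), ] <- vals
  }
  for (v in g$nodes)
    if (anyNA(cpts[[v]]))
      stop(path, ": incomplete CPT for ", v, call. = FALSE)
  cpts
}

write_plain_network <- function(bn, path) {
  g <- if (inherits(bn, "discrete_bn")) bn$structure else bn
  arities <- if (inherits(bn, "discrete_bn")) bn$arities else
    stats::setNames(rep(2L, length(g$nodes)), g$nodes)
  out <- sprintf("#node %s %d", g$nodes, arities)
  if (nrow(g$arcs) > 0L)
    out <- c(out, sprintf("%s\t%s", g$arcs[, 1L], g$arcs[, 2L]))
  writeLines(out, path)
  if (inherits(bn, "discrete_bn")) {
    rows <- character(0)
    for (v in g$nodes) {
      ps <- parents(g, v)
      confs <- all_configs(bn$arities[ps])
      cpt <- bn$cpts[[v]]
      conf_str <- if (length(ps) == 0L) "." else
        apply(confs, 1L, paste, collapse = ",")
      rows <- c(rows, sprintf("%s\t%s\t%s", v, conf_str,
                              apply(cpt, 1L, function(r)
                                paste(format(r, digits = 17), collapse = ","))))
    }
    writeLines(rows, paste0(path, ".cpt"))
  }
}

#' Read a discrete dataset from CSV
#'
#' Expects a header row of variable names and integer state codes starting
#' at 0, one record per line.
#'
#' @param path CSV file path.
#' @param arities optional named arities; inferred from the data otherwise.
#' @return a `discrete_dataset`.
#' @export
read_dataset <- function(path, arities = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  discrete_dataset(df, arities)
}

#' Write a discrete dataset to CSV
#' @param data a `discrete_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data$records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
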