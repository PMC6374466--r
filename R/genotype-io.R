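#' Read a GenePop-format genotype file
#'
#' Accepts both 2-digit and 3-digit allele encodings (detected from call
#' width). The first line is a title; locus names follow one per line or
#' comma-separated on a single line; population blocks are introduced by a
#' line reading `pop` (any case) and rows are `id , call call ...`.
#' `00`/`000` halves mark a missing call (a call with either half zero is
#' treated as wholly missing).
#'
#' @param path file path.
#' @param pop_names optional character vector naming the population blocks in
#'   order; default is the identifier of each block's first individual.
#' @return a [genotype_table()] (without region/coords metadata; see
#'   [read_metadata()]).
#' @export
read_genepop <- function(path, pop_names = NULL) {
  stop_if(!file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  stop_if(length(lines) < 3, "file too short to be GenePop")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  stop_if(is.na(first_pop), "no 'pop' line found")
  loci <- trimws(unlist(strsplit(lines[2:(first_pop - 1)], ",")))
  loci <- loci[nzchar(loci)]
  stop_if(length(loci) == 0, "no locus names before first 'pop'")

  ids <- character(); pops <- integer()
  rows <- list()
  block <- 0L
  digits <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") { block <- block + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    stop_if(length(parts) < 2, "line %d: expected 'id , calls'", ln)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    stop_if(length(toks) != length(loci),
            "line %d: %d calls for %d loci (ragged row)", ln,
            length(toks), length(loci))
    w <- unique(nchar(toks))
    stop_if(length(w) != 1 || w %% 2 != 0 || !(w %in% c(4L, 6L)),
            "line %d: allele strings must be uniformly 4 or 6 digits", ln)
    if (is.na(digits)) digits <- w %/% 2L
    stop_if(w %/% 2L != digits, "line %d: mixed allele encodings", ln)
    h1 <- as.integer(substr(toks, 1, digits))
    h2 <- as.integer(substr(toks, digits + 1, 2 * digits))
    stop_if(anyNA(h1) || anyNA(h2), "line %d: non-numeric allele call", ln)
    miss <- h1 == 0L | h2 == 0L
    h1[miss] <- NA_integer_; h2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, block)
    rows[[length(rows) + 1L]] <- rbind(h1, h2)
  }
  stop_if(length(rows) == 0, "no individuals found")
  a1 <- t(vapply(rows, function(r) r[1, ], integer(length(loci))))
  a2 <- t(vapply(rows, function(r) r[2, ], integer(length(loci))))
  if (length(loci) == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  nblock <- max(pops)
  if (is.null(pop_names)) {
    pop_names <- vapply(seq_len(nblock),
                        function(b) ids[which(pops == b)[1]], "")
  }
  stop_if(length(pop_names) != nblock, "pop_names length != %d blocks", nblock)
  genotype_table(a1, a2, loci, ids, pop_names[pops])
}

#' Write a genotype table as a GenePop file
#'
#' @param table a `genotype_table`.
#' @param path output path.
#' @param digits 2 or 3 digit allele encoding (default 3).
#' @param title first (comment) line.
#' @export
write_genepop <- function(table, path, digits = 3, title = "reefconnect export") {
  stop_if(!digits %in% c(2, 3), "digits must be 2 or 3")
  stop_if(max(c(table$a1, table$a2), na.rm = TRUE) >= 10^digits,
          "allele labels too wide for %d-digit encoding", digits)
  fmt <- sprintf("%%0%dd%%0%dd", digits, digits)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(table$loci, con)
  for (p in pop_levels(table)) {
    writeLines("pop", con)
    for (i in which(table$pop == p)) {
      calls <- vapply(seq_len(n_loci(table)), function(l) {
        if (is.na(table$a1[i, l])) {
          sprintf(fmt, 0L, 0L)
        } else sprintf(fmt, table$a1[i, l], table$a2[i, l])
      }, "")
      writeLines(paste0(table$id[i], " , ", paste(calls, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write / read the per-individual metadata table
#'
#' CSV with columns `id`, `pop`, `lat`, `lon`, `region`; the companion of a
#' GenePop file (which carries no coordinates or region classes).
#'
#' @param table a `genotype_table` with coords/region metadata.
#' @param path CSV path.
#' @export
write_metadata <- function(table, path) {
  co <- table$coords
  md <- data.frame(id = table$id, pop = table$pop,
                   lat = if (!is.null(co)) co$lat[match(table$pop, co$pop)] else NA,
                   lon = if (!is.null(co)) co$lon[match(table$pop, co$pop)] else NA,
                   region = table$region %||% NA)
  utils::write.csv(md, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @param genotypes a `genotype_table` to attach the metadata to.
#' @return `read_metadata`: the genotype table with region and coords filled.
#' @export
read_metadata <- function(genotypes, path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("id", "pop") %in% names(md)), "metadata needs id and pop")
  i <- match(genotypes$id, md$id)
  stop_if(anyNA(i), "metadata missing individuals: %s",
          paste(utils::head(genotypes$id[is.na(i)], 5), collapse = ", "))
  pop <- md$pop[i]
  region <- if ("region" %in% names(md)) md$region[i]
  coords <- NULL
  if (all(c("lat", "lon") %in% names(md))) {
    coords <- unique(data.frame(pop = md$pop, lat = md$lat, lon = md$lon))
    coords <- coords[coords$pop %in% pop, ]
  }
  genotype_table(genotypes$a1, genotypes$a2, genotypes$loci, genotypes$id,
                 pop, region = region, coords = coords)
}

#' Read a cluster-membership (Q) matrix
#'
#' Whitespace-delimited table: individual identifier followed by one
#' membership fraction per cluster. One file per clustering solution (K).
#'
#' @param path file path.
#' @return numeric matrix (individuals x clusters) with identifier rownames.
#' @export
read_qmatrix <- function(path) {
  q <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(q[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- q[[1]]
  colnames(m) <- paste0("cluster", seq_len(ncol(m)))
  bad <- abs(rowSums(m) - 1) > 1e-6
  stop_if(any(bad), "Q rows not summing to 1: %s",
          paste(utils::head(rownames(m)[bad], 5), collapse = ", "))
  m
}

filter_report <- function(ind_removed, pops_removed, loci_removed,
                          n_in, n_out) {
  structure(list(individuals_removed = ind_removed,
                 populations_removed = pops_removed,
                 loci_removed = loci_removed,
                 n_input = n_in, n_retained = n_out),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d -> %d individuals (%d removed)\n",
              x$n_input, x$n_retained, x$n_input - x$n_retained))
  if (nrow(x$individuals_removed))
    print(table(x$individuals_removed$reason))
  if (length(x$loci_removed))
    cat("loci removed:", paste(x$loci_removed, collapse = ", "), "\n")
  if (nrow(x$populations_removed))
    cat("populations removed:",
        paste(x$populations_removed$pop, collapse = ", "), "\n")
  invisible(x)
}

#' Retain individuals of one cryptic lineage
#'
#' Keeps individuals whose membership in the designated cluster is at least
#' `threshold` (inclusive) in *every* supplied clustering solution, the rule
#' used to isolate the lineage present in both temperate and subtropical
#' regions before any population-genetic statistics.
#'
#' @param table a `genotype_table`.
#' @param q a Q matrix ([read_qmatrix()]) or list of them, one per K block.
#' @param target_cluster column (index or name) of the designated cluster in
#'   each block; recycled if scalar.
#' @param threshold membership threshold (default 0.70).
#' @return list `table` (filtered) and `report` (a `filter_report`).
#' @export
filter_lineage <- function(table, q, target_cluster = 1, threshold = 0.70) {
  if (is.matrix(q)) q <- list(q)
  target_cluster <- rep_len(target_cluster, length(q))
  keep <- rep(TRUE, n_ind(table))
  for (b in seq_along(q)) {
    miss <- setdiff(table$id, rownames(q[[b]]))
    stop_if(length(miss) > 0, "individuals missing from Q block %d: %s", b,
            paste(utils::head(miss, 10), collapse = ", "))
    keep <- keep & q[[b]][table$id, target_cluster[b]] >= threshold
  }
  removed <- data.frame(id = table$id[!keep],
                        reason = rep("lineage_membership", sum(!keep)))
  out <- if (all(!keep)) {
    stop("lineage filter removed every individual", call. = FALSE)
  } else gt_subset(table, ind = keep)
  list(table = out,
       report = filter_report(removed, data.frame(pop = character(),
                                                  reason = character()),
                              character(), n_ind(table), n_ind(out)))
}

#' Drop populations with too few multilocus genotypes
#'
#' Populations whose count of distinct multilocus genotypes (MLGs) is below
#' `min_mlg` are removed entirely: very small samples are unsuitable for
#' population-genetic inference.
#'
#' @param table a `genotype_table`.
#' @param min_mlg inclusive minimum MLG count (default 9).
#' @param partition optional precomputed [detect_clones()] result.
#' @return list `table`, `report`.
#' @export
filter_populations <- function(table, min_mlg = 9, partition = NULL) {
  part <- partition %||% detect_clones(table)
  mlg <- part$mlg_per_pop
  drop <- names(mlg)[mlg < min_mlg]
  keep <- !(table$pop %in% drop)
  stop_if(all(!keep), "population filter removed every population")
  out <- gt_subset(table, ind = keep)
  list(table = out,
       report = filter_report(
         data.frame(id = table$id[!keep],
                    reason = rep("population_below_min_mlg", sum(!keep))),
         data.frame(pop = drop,
                    reason = rep(sprintf("mlg < %d", min_mlg), length(drop))),
         character(), n_ind(table), n_ind(out)))
}

#' Drop named loci
#'
#' Removes loci excluded on quality grounds (e.g. a locus with suspected
#' null alleles) before analysis.
#'
#' @param table a `genotype_table`.
#' @param names locus names to drop (must exist; dropping all loci refused).
#' @return a `genotype_table` without the named loci.
#' @export
exclude_loci <- function(table, names) {
  if (length(names) == 0) return(table)
  unknown <- setdiff(names, table$loci)
  stop_if(length(unknown) > 0, "unknown locus name(s): %s",
          paste(unknown, collapse = ", "))
  keep <- setdiff(table$loci, names)
  stop_if(length(keep) == 0, "refusing to exclude every locus")
  gt_subset(table, loci = keep)
}
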