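## Readers and writers for every external representation the pipeline
## touches. Coordinates are 1-based inclusive throughout (GFF3 convention);
## the intergenic distance between consecutive genes is
## next.start - prev.end - 1.

#' Read a gene-by-sample count table and its taxon map
#'
#' The count file is a TSV whose first column holds gene ids and whose
#' remaining columns hold per-sample non-negative integer counts. The taxon
#' map is a two-column TSV (`gene_id`, `taxon`). Sample order is preserved.
#'
#' @param path count TSV.
#' @param taxonPath gene-to-taxon TSV.
#' @param sampleDataPath optional TSV of sample metadata; first column must
#'   hold the sample ids.
#' @return a [CommunityCounts-class] object.
#' @export
readCounts <- function(path, taxonPath, sampleDataPath = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count file needs a gene-id column plus >= 1 sample")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric count for gene '%s', sample '%s'",
                 genes[bad[1]], colnames(df)[-1][bad[2]]))
  }
  bad <- which(mat < 0 | mat != floor(mat) | is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("count must be a non-negative integer: gene '%s', sample '%s' has value %s",
                 genes[bad[1, 1]], colnames(mat)[bad[1, 2]], mat[bad[1, , drop = FALSE]]))
  }
  rownames(mat) <- genes
  tm <- utils::read.delim(taxonPath, stringsAsFactors = FALSE)
  if (ncol(tm) < 2) stop("taxon map needs columns gene_id, taxon")
  taxa <- stats::setNames(as.character(tm[[2]]), as.character(tm[[1]]))
  cd <- NULL
  if (!is.null(sampleDataPath)) {
    sd <- utils::read.delim(sampleDataPath, stringsAsFactors = FALSE)
    rownames(sd) <- as.character(sd[[1]])
    cd <- S4Vectors::DataFrame(sd[colnames(mat), -1, drop = FALSE])
  }
  CommunityCounts(mat, taxa = taxa, colData = cd)
}

#' Write a CommunityCounts object back to TSV
#'
#' Inverse of [readCounts()]: `readCounts(writeCounts(x))` reproduces the
#' parsed object.
#'
#' @param x a [CommunityCounts-class].
#' @param path destination count TSV.
#' @param taxonPath destination taxon-map TSV.
#' @return invisibly, the paths written.
#' @export
writeCounts <- function(x, path, taxonPath) {
  m <- counts(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tm <- data.frame(gene_id = rownames(m), taxon = unname(geneTaxa(x)))
  utils::write.table(tm, taxonPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, taxonPath))
}

## GMM flat-file dialect: header line "<id>\t<name>", then one line per
## step; "," separates alternatives within a step, "+" joins the members of
## a complex; a line "///" terminates the module.

#' Read a metabolic-module database in the GMM flat format
#'
#' @param path flat file (see Details).
#' @details Each module starts with a tab-separated header line (module id,
#'   module name), followed by one line per reaction step. Within a step
#'   line, `","` separates alternative KOs and `"+"` joins the members of a
#'   complex; `"///"` ends the module.
#' @return a [ModuleDatabase-class].
#' @export
readGmmDatabase <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  mods <- list()
  id <- NULL; name <- ""; steps <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (!length(steps)) stop(sprintf("module '%s' has no steps", id))
    mods[[length(mods) + 1L]] <<- methods::new(
      "ModuleDefinition", id = id, name = name, steps = steps)
    id <<- NULL; name <<- ""; steps <<- list()
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (ln == "///") { flush(); next }
    if (is.null(id)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      id <- parts[1]
      name <- if (length(parts) > 1) parts[2] else ""
    } else {
      alts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      steps[[length(steps) + 1L]] <- lapply(
        alts, function(a) trimws(strsplit(a, "+", fixed = TRUE)[[1]]))
    }
  }
  flush()
  ModuleDatabase(mods)
}

#' Write a ModuleDatabase in the GMM flat format
#' @param db a [ModuleDatabase-class].
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
writeGmmDatabase <- function(db, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in db@modules) {
    writeLines(paste(m@id, m@name, sep = "\t"), con)
    for (s in m@steps)
      writeLines(paste(vapply(s, paste, character(1), collapse = "+"),
                       collapse = ","), con)
    writeLines("///", con)
  }
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Imports a GFF3 file, keeps `gene` features (or all features if none are
#' typed `gene`), and returns them sorted by contig and start. Gene ids are
#' taken from the `ID` attribute.
#'
#' @param path GFF3 file.
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id` and,
#'   when present, `product`.
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  id <- gr$ID
  if (is.null(id)) stop("GFF3 features need an ID attribute")
  gr$gene_id <- as.character(id)
  if (is.null(gr$product)) gr$product <- NA_character_
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  gr
}

#' Read a KO assignment table
#'
#' TSV with columns `gene_id` and `ko`; the `ko` field may hold a
#' comma-separated list, which is expanded to one row per (gene, KO). Genes
#' with an empty `ko` field are dropped.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `gene_id`, `ko`.
#' @export
readKoTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "ko") %in% colnames(df)))
    stop("KO table needs columns gene_id, ko")
  kos <- strsplit(as.character(df$ko), ",", fixed = TRUE)
  out <- data.frame(
    gene_id = rep(df$gene_id, lengths(kos)),
    ko = trimws(unlist(kos)),
    stringsAsFactors = FALSE)
  out[nzchar(out$ko), , drop = FALSE]
}

#' Read BGC region definitions
#'
#' A simplified TSV stand-in for antiSMASH region output: one row per
#' region with columns `region_id`, `taxon`, `contig`, `product_class`,
#' `member_genes` (comma-separated, any order) and `core_genes`
#' (comma-separated subset of the members). Gene coordinates are looked up
#' in `genes` and members are returned sorted by start; regions are ordered
#' by contig and the start of their first gene.
#'
#' @param path region TSV.
#' @param genes [GenomicRanges::GRanges] of gene annotations (from
#'   [readGff3()]).
#' @return `data.frame` with one row per member gene: `region_id`, `taxon`,
#'   `contig`, `product_class`, `gene_id`, `start`, `end`, `core`.
#' @export
readBgcRegions <- function(path, genes) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "taxon", "contig", "product_class",
            "member_genes", "core_genes")
  if (!all(need %in% colnames(df)))
    stop("region table needs columns: ", paste(need, collapse = ", "))
  lut <- stats::setNames(seq_along(genes$gene_id), genes$gene_id)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    members <- trimws(strsplit(df$member_genes[i], ",", fixed = TRUE)[[1]])
    cores <- if (nzchar(df$core_genes[i]))
      trimws(strsplit(df$core_genes[i], ",", fixed = TRUE)[[1]]) else character(0)
    badCore <- setdiff(cores, members)
    if (length(badCore))
      stop(sprintf("region '%s': core gene(s) %s absent from member list",
                   df$region_id[i], paste(badCore, collapse = ", ")))
    unknown <- setdiff(members, names(lut))
    if (length(unknown))
      stop(sprintf("region '%s' references unknown gene id(s): %s",
                   df$region_id[i], paste(unknown, collapse = ", ")))
    idx <- lut[members]
    out <- data.frame(
      region_id = df$region_id[i], taxon = df$taxon[i], contig = df$contig[i],
      product_class = df$product_class[i], gene_id = members,
      start = GenomicRanges::start(genes)[idx],
      end = GenomicRanges::end(genes)[idx],
      core = members %in% cores, stringsAsFactors = FALSE)
    out[order(out$start), , drop = FALSE]
  })
  ord <- order(vapply(rows, function(r) r$contig[1], character(1)),
               vapply(rows, function(r) r$start[1], numeric(1)))
  out <- do.call(rbind, rows[ord])
  rownames(out) <- NULL
  out
}

#' Write BGC region definitions
#' @param regions per-gene region `data.frame` as returned by
#'   [readBgcRegions()] (or the generator).
#' @param path destination TSV.
#' @return invisibly, `path`.
#' @export
writeBgcRegions <- function(regions, path) {
  sp <- split(regions, regions$region_id)
  df <- do.call(rbind, lapply(sp, function(r) data.frame(
    region_id = r$region_id[1], taxon = r$taxon[1], contig = r$contig[1],
    product_class = r$product_class[1],
    member_genes = paste(r$gene_id[order(r$start)], collapse = ","),
    core_genes = paste(r$gene_id[r$core][order(r$start[r$core])], collapse = ","),
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Fixed column order of edge tables; see correlateFeatures() for semantics.
.edgeCols <- c("node_a", "node_b", "taxon_a", "taxon_b", "kind_a", "kind_b",
               "r", "rho", "n_shared", "cross_species", "removed_by",
               "weight", "shared_ko_fraction")

#' Write a co-expression edge table to TSV
#'
#' Columns (in fixed order): `node_a`, `node_b`, `taxon_a`, `taxon_b`,
#' `kind_a`, `kind_b`, `r`, `rho`, `n_shared`, `cross_species`,
#' `removed_by`, and, when present, `weight` and `shared_ko_fraction`.
#'
#' @param edges edge `data.frame` (see [correlateFeatures()]).
#' @param path destination TSV.
#' @return invisibly, `path`.
#' @export
writeEdgeTable <- function(edges, path) {
  cols <- intersect(.edgeCols, colnames(edges))
  utils::write.table(edges[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a co-expression edge table written by [writeEdgeTable()]
#' @param path TSV file.
#' @return edge `data.frame`.
#' @export
readEdgeTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Convert a CoexpressionNetwork to an igraph object
#'
#' Node attributes `taxon` and `kind` and all edge columns are carried over.
#' @param x a [CoexpressionNetwork-class].
#' @return an [igraph::graph] object.
#' @export
asIgraph <- function(x) {
  stopifnot(methods::is(x, "CoexpressionNetwork"))
  e <- x@edges
  igraph::graph_from_data_frame(
    d = e[, c("node_a", "node_b",
              setdiff(colnames(e), c("node_a", "node_b"))), drop = FALSE],
    directed = FALSE, vertices = x@nodes)
}

#' Write a CoexpressionNetwork as GraphML
#' @param x a [CoexpressionNetwork-class].
#' @param path destination `.graphml` file.
#' @return invisibly, `path`.
#' @export
writeGraphML <- function(x, path) {
  g <- asIgraph(x)
  ## igraph's GraphML writer rejects logical attributes
  for (a in igraph::edge_attr_names(g))
    if (is.logical(igraph::edge_attr(g, a)))
      g <- igraph::set_edge_attr(g, a, value = as.character(igraph::edge_attr(g, a)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialize a SyntheticTruth object to JSON
#' @param truth a [SyntheticTruth-class].
#' @param path destination JSON file.
#' @return invisibly, `path`.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(
    planted = truth@planted, genePrograms = truth@genePrograms,
    confounder = truth@confounder,
    relAbundance = list(taxa = rownames(truth@relAbundance),
                        samples = colnames(truth@relAbundance),
                        values = unname(truth@relAbundance)),
    latent = lapply(truth@latent, unname),
    latentTaxa = names(truth@latent),
    expectedPresence = list(taxa = rownames(truth@expectedPresence),
                            samples = colnames(truth@expectedPresence),
                            values = unname(truth@expectedPresence)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a SyntheticTruth object written by [writeTruth()]
#' @param path JSON file.
#' @return a [SyntheticTruth-class].
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## jsonlite stores matrices row-major as nested arrays
  ra <- do.call(rbind, lapply(seq_along(obj$relAbundance$taxa),
                              function(i) obj$relAbundance$values[i, ]))
  dimnames(ra) <- list(obj$relAbundance$taxa, obj$relAbundance$samples)
  ep <- do.call(rbind, lapply(seq_along(obj$expectedPresence$taxa),
                              function(i) obj$expectedPresence$values[i, ]))
  dimnames(ep) <- list(obj$expectedPresence$taxa, obj$expectedPresence$samples)
  lat <- obj$latent
  names(lat) <- obj$latentTaxa
  lat <- lapply(lat, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(NULL, obj$relAbundance$samples)
    m
  })
  methods::new("SyntheticTruth",
    planted = as.data.frame(obj$planted),
    genePrograms = as.data.frame(obj$genePrograms),
    confounder = as.numeric(obj$confounder),
    relAbundance = ra, latent = lat,
    expectedPresence = ep == 1 | ep == TRUE)
}
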