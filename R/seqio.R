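## Sequence and cluster I/O.  FASTA goes through Biostrings; the cluster
## descriptor is this package's own JSON/TSV dialect (documented in README)
## because upstream GenBank/antiSMASH records are out of scope.

#' Read a protein FASTA file
#'
#' Reads a multi-record protein FASTA file into an [Biostrings::AAStringSet].
#' Sequences are whitespace-stripped and uppercased; the FASTA header up to
#' the first whitespace becomes the record id (kept unique), the remainder is
#' stored as `mcols(x)$description`.  Ambiguity codes `B`, `Z` and `U` are
#' mapped to `X` with a warning so that substitution-matrix lookups stay
#' total; any other non-standard character is rejected with its position.
#'
#' @param path path to a FASTA file.
#' @return an `AAStringSet`, names = ids, with a `description` metadata
#'   column.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a toy", "MKV", ">b", "mqq"), tf)
#' readProteins(tf)
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readBStringSet(path)  # raw read; validation is ours
  if (length(aa) == 0L) stop("no records in FASTA file: ", path)
  hdr <- names(aa)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- cleanSequences(as.character(aa), ids)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write proteins to FASTA
#'
#' @param x an `AAStringSet` (descriptions taken from `mcols(x)$description`
#'   when present) or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteins <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  out <- x
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc)) {
    nm <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
    names(out) <- nm
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

## Uppercase, strip whitespace, map B/Z/U -> X (warning), reject anything
## else outside the 20 standard residues + X.
cleanSequences <- function(seqs, ids) {
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  mapped <- grepl("[BZU]", seqs)
  if (any(mapped)) {
    warning("ambiguous residues B/Z/U mapped to X in: ",
            paste(ids[mapped], collapse = ", "))
    seqs <- gsub("[BZU]", "X", seqs)
  }
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET_STRICT, collapse = "")),
                 seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character '%s' at position %d of '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  if (any(!nzchar(seqs)))
    stop("empty sequence for: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs
}

#' Construct a GeneCluster
#'
#' @param clusterId cluster identifier.
#' @param genes named character vector or `AAStringSet` of protein
#'   sequences (names = gene ids).
#' @param annotation free-text annotation per gene (recycled `""`).
#' @param role role tags; when `NULL`, pre-filled from annotation keywords
#'   via [annotationRole()].
#' @return a [GeneCluster-class].
#' @examples
#' geneCluster("bgc1", c(g1 = "MKVH", g2 = "MAARD"),
#'             annotation = c("NRPS", "sulfotransferase"))
#' @export
geneCluster <- function(clusterId, genes, annotation = NULL, role = NULL) {
  if (is.character(genes)) {
    ids <- names(genes)
    genes <- Biostrings::AAStringSet(cleanSequences(genes, ids))
    names(genes) <- ids
  }
  n <- length(genes)
  if (is.null(annotation)) annotation <- rep("", n)
  if (is.null(role)) role <- annotationRole(annotation)
  new("GeneCluster", clusterId = as.character(clusterId), genes = genes,
      annotation = as.character(annotation), role = role)
}

#' Role tag from an annotation string
#'
#' Keyword pre-fill used by [readCluster()]: annotations mentioning
#' "sulfotransferase" tag the gene `sulfotransferase`; mentions of NRPS /
#' synthetase / condensation / adenylation tag it `nrps`; everything else is
#' `unknown`.
#'
#' @param annotation character vector of free-text annotations.
#' @return character vector of role tags.
#' @export
annotationRole <- function(annotation) {
  role <- rep("unknown", length(annotation))
  role[grepl("nrps|synthetase|non-?ribosomal|adenylation|condensation",
             annotation, ignore.case = TRUE)] <- "nrps"
  role[grepl("sulfotransferase", annotation, ignore.case = TRUE)] <-
    "sulfotransferase"
  role
}

#' Read a cluster descriptor (JSON or TSV)
#'
#' The JSON dialect is
#' `{"cluster_id": "...", "genes": [{"gene_id": "...", "sequence": "...",
#' "annotation": "..."}]}`; the TSV form has columns `gene_id`, `sequence`,
#' `annotation` (cluster id = file stem).  Role tags are pre-filled from
#' annotation keywords.  Duplicate gene ids or missing sequences are
#' rejected.
#'
#' @param path path to a `.json` or `.tsv` file.
#' @return a [GeneCluster-class].
#' @export
readCluster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$genes) || !is.data.frame(obj$genes))
      stop("cluster JSON must contain a 'genes' array")
    g <- obj$genes
    cid <- if (!is.null(obj$cluster_id)) obj$cluster_id else
      sub("\\.[^.]*$", "", basename(path))
  } else {
    g <- utils::read.delim(path, stringsAsFactors = FALSE)
    cid <- sub("\\.[^.]*$", "", basename(path))
  }
  need <- c("gene_id", "sequence")
  if (!all(need %in% names(g)))
    stop("cluster descriptor needs columns gene_id and sequence")
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in cluster: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  if (any(is.na(g$sequence) | !nzchar(g$sequence)))
    stop("missing sequence for gene(s): ",
         paste(g$gene_id[is.na(g$sequence) | !nzchar(g$sequence)],
               collapse = ", "))
  ann <- if ("annotation" %in% names(g)) {
    a <- as.character(g$annotation); a[is.na(a)] <- ""; a
  } else rep("", nrow(g))
  geneCluster(cid, stats::setNames(as.character(g$sequence), g$gene_id), ann)
}

#' Write a cluster descriptor
#'
#' Inverse of [readCluster()]; `read(write(x)) == x` up to role re-derivation.
#'
#' @param cluster a [GeneCluster-class].
#' @param path output path ending in `.json` or `.tsv`.
#' @return `path`, invisibly.
#' @export
writeCluster <- function(cluster, path) {
  stopifnot(is(cluster, "GeneCluster"))
  g <- data.frame(gene_id = names(cluster@genes),
                  sequence = as.character(cluster@genes),
                  annotation = cluster@annotation,
                  stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(cluster_id = cluster@clusterId, genes = g),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

verdictToRow <- function(v) {
  crit <- v@criteria[CRITERION_IDS]
  row <- data.frame(cluster_id = v@clusterId,
                    call = v@call, n_passed = v@nPassed,
                    te_gene = v@teGene, a_gene = v@aGene,
                    stringsAsFactors = FALSE)
  for (id in CRITERION_IDS) {
    row[[id]] <- crit[[id]]@passed
    row[[paste0(id, "_evidence")]] <- crit[[id]]@evidence
  }
  row
}

#' Write a screening report
#'
#' One row per cluster with per-criterion pass/fail, supporting evidence and
#' the aggregate call.  TSV and/or JSON are written depending on which paths
#' are given; an empty verdict list yields a header-only TSV and an empty
#' JSON array.
#'
#' @param verdicts list of [ClusterVerdict-class] objects.
#' @param tsv,json output paths (`NULL` = skip that format).
#' @return data.frame of the report rows, invisibly.
#' @export
writeReport <- function(verdicts, tsv = NULL, json = NULL) {
  stopifnot(all(vapply(verdicts, is, logical(1), "ClusterVerdict")))
  if (length(verdicts)) {
    tab <- do.call(rbind, lapply(verdicts, verdictToRow))
  } else {
    tab <- verdictToRow(emptyVerdict("x"))[0, ]
  }
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(tab, json, auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Re-read a JSON screening report as verdicts
#'
#' Round-trip inverse of [writeReport()]'s JSON output.
#'
#' @param path JSON report path.
#' @return list of [ClusterVerdict-class] objects.
#' @export
readReport <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(tab) == 0L) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    crit <- lapply(CRITERION_IDS, function(id) {
      new("CriterionResult", id = id, passed = tab[[id]][i],
          evidence = tab[[paste0(id, "_evidence")]][i])
    })
    names(crit) <- CRITERION_IDS
    new("ClusterVerdict", clusterId = tab$cluster_id[i], criteria = crit,
        nPassed = as.integer(tab$n_passed[i]), call = tab$call[i],
        teGene = tab$te_gene[i], aGene = tab$a_gene[i])
  })
}

emptyVerdict <- function(clusterId, reason = "no TE domain") {
  crit <- lapply(CRITERION_IDS, function(id)
    new("CriterionResult", id = id, passed = FALSE, evidence = reason))
  names(crit) <- CRITERION_IDS
  new("ClusterVerdict", clusterId = clusterId, criteria = crit,
      nPassed = 0L, call = "rejected", teGene = NA_character_,
      aGene = NA_character_)
}
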