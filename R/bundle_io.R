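# Writing a simulated study bundle to plain-text files (GTF, BED,
# bedGraph, TSV) and reading it back. File output is deterministic:
# identical bundles produce byte-identical trees.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated study bundle to a directory
#'
#' Emits every layer as plain-text files in the standard formats: gene
#' models as GTF, peaks as BED6+2, signal as bedGraph, tables as TSV, and
#' the truth bundle as TSVs under `truth/`.
#'
#' @param bundle a `sim_bundle` from [simulate_study()] or [null_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  mkd <- function(...) {
    p <- file.path(dir, ...)
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
    p
  }
  mkd(".")
  write_tsv(bundle$genome, file.path(dir, "genome.tsv"))
  write_gtf_genes(bundle$genes, file.path(dir, "genes.gtf"))
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))

  ad <- mkd("atac")
  for (s in names(bundle$atac)) for (r in names(bundle$atac[[s]]))
    write_peaks(bundle$atac[[s]][[r]], file.path(ad, sprintf("%s_%s.bed", s, r)))
  td <- mkd("tracks")
  for (s in names(bundle$tracks))
    write_bedgraph(bundle$tracks[[s]], file.path(td, sprintf("atac_%s.bedgraph", s)))

  if (!is.null(bundle$refs)) {
    rd <- mkd("refs")
    for (lab in names(bundle$refs))
      write_regions_bed(bundle$refs[[lab]], file.path(rd, paste0(lab, ".bed")))
    manifest <- bundle$ref_labels
    manifest$path <- file.path("refs", paste0(manifest$label, ".bed"))
    write_tsv(manifest, file.path(dir, "refs_manifest.tsv"))
  }
  if (!is.null(bundle$chip)) {
    cd <- mkd("chip")
    for (f in names(bundle$chip)) {
      write_regions_bed(bundle$chip[[f]]$reg_peaks,
                        file.path(cd, sprintf("%s_reg_peaks.bed", f)))
    }
    write_bedgraph(bundle$chip[[1]]$reg_track,
                   file.path(cd, "track_regeneration.bedgraph"))
    write_bedgraph(bundle$chip[[1]]$ctl_track,
                   file.path(cd, "track_control.bedgraph"))
  }
  if (!is.null(bundle$conservation))
    write_bedgraph(bundle$conservation, file.path(dir, "conservation.bedgraph"))
  if (!is.null(bundle$masks)) {
    md <- mkd("masks")
    for (sp in names(bundle$masks))
      write_regions_bed(bundle$masks[[sp]], file.path(md, paste0(sp, ".bed")))
    write_tsv(data.frame(species = names(bundle$masks),
                         path = file.path("masks", paste0(names(bundle$masks), ".bed"))),
              file.path(dir, "masks_manifest.tsv"))
  }
  if (!is.null(bundle$starr))
    write_regions_bed(bundle$starr, file.path(dir, "starr.bed"))
  if (!is.null(bundle$orthologs))
    write_tsv(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  if (!is.null(bundle$species_expression)) {
    sd <- mkd("species")
    for (sp in names(bundle$species_expression))
      write_tsv(bundle$species_expression[[sp]],
                file.path(sd, paste0(sp, ".tsv")))
  }
  if (!is.null(bundle$zf)) {
    zd <- mkd("zf")
    write_gtf_genes(bundle$zf$genes, file.path(zd, "genes.gtf"))
    for (s in c("uninjured", "injured")) for (r in names(bundle$zf[[s]]))
      write_peaks(bundle$zf[[s]][[r]], file.path(zd, sprintf("%s_%s.bed", s, r)))
    write_regions_bed(bundle$zf$embryo_open, file.path(zd, "embryo_open.bed"))
  }
  if (!is.null(bundle$qpcr))
    write_tsv(bundle$qpcr, file.path(dir, "qpcr.tsv"))

  # truth
  tr <- bundle$truth
  trd <- mkd("truth")
  if (!is.null(tr$de)) write_tsv(tr$de, file.path(trd, "de.tsv"))
  if (!is.null(tr$de_labels))
    write_tsv(data.frame(gene_id = tr$de_labels), file.path(trd, "de_labels.tsv"))
  if (!is.null(tr$clusters)) {
    cl <- tr$clusters
    cl$members <- vapply(cl$members, paste, character(1), collapse = ",")
    write_tsv(cl, file.path(trd, "clusters.tsv"))
  }
  if (!is.null(tr$drre)) write_tsv(tr$drre, file.path(trd, "drre.tsv"))
  if (!is.null(tr$usage)) write_tsv(tr$usage, file.path(trd, "usage.tsv"))
  if (!is.null(tr$activity)) write_tsv(tr$activity, file.path(trd, "activity.tsv"))
  if (!is.null(tr$species)) write_tsv(tr$species, file.path(trd, "species.tsv"))
  if (!is.null(tr$core))
    write_tsv(data.frame(gene_id = tr$core), file.path(trd, "core.tsv"))
  if (!is.null(tr$zf)) write_tsv(tr$zf, file.path(trd, "zf.tsv"))
  if (!is.null(tr$qpcr_folds))
    write_tsv(tr$qpcr_folds, file.path(trd, "qpcr_folds.tsv"))
  invisible(dir)
}

#' Read a study bundle from a directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a `sim_bundle` list (without the generating `config`).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  has <- function(...) file.exists(p(...))
  bundle <- list(genome = read_tsv(p("genome.tsv")),
                 genes = read_gtf_genes(p("genes.gtf")),
                 expression = read_expression(p("expression.tsv")))
  if (dir.exists(p("atac"))) {
    atac <- list()
    for (f in sort(list.files(p("atac"), pattern = "\\.bed$"))) {
      key <- sub("\\.bed$", "", f)
      parts <- strsplit(key, "_")[[1]]
      s <- parts[1]; r <- parts[2]
      if (is.null(atac[[s]])) atac[[s]] <- list()
      atac[[s]][[r]] <- read_peaks(p("atac", f))
    }
    bundle$atac <- atac
  }
  if (dir.exists(p("tracks"))) {
    bundle$tracks <- list()
    for (f in sort(list.files(p("tracks"), pattern = "\\.bedgraph$"))) {
      s <- sub("^atac_", "", sub("\\.bedgraph$", "", f))
      bundle$tracks[[s]] <- read_bedgraph(p("tracks", f))
    }
  }
  if (has("refs_manifest.tsv")) {
    man <- read_tsv(p("refs_manifest.tsv"))
    bundle$ref_labels <- man[, c("label", "stage", "tissue")]
    bundle$refs <- stats::setNames(
      lapply(man$path, function(f) read_regions_bed(p(f))), man$label)
  }
  if (dir.exists(p("chip"))) {
    regt <- read_bedgraph(p("chip", "track_regeneration.bedgraph"))
    ctlt <- read_bedgraph(p("chip", "track_control.bedgraph"))
    feats <- sub("_reg_peaks\\.bed$", "",
                 list.files(p("chip"), pattern = "_reg_peaks\\.bed$"))
    bundle$chip <- stats::setNames(lapply(feats, function(f)
      list(reg_peaks = read_regions_bed(p("chip", paste0(f, "_reg_peaks.bed"))),
           reg_track = regt, ctl_track = ctlt)), feats)
  }
  if (has("conservation.bedgraph"))
    bundle$conservation <- read_bedgraph(p("conservation.bedgraph"))
  if (has("masks_manifest.tsv")) {
    man <- read_tsv(p("masks_manifest.tsv"))
    bundle$masks <- stats::setNames(
      lapply(man$path, function(f) read_regions_bed(p(f))), man$species)
  }
  if (has("starr.bed")) bundle$starr <- read_regions_bed(p("starr.bed"))
  if (has("orthologs.tsv")) bundle$orthologs <- read_ortholog_map(p("orthologs.tsv"))
  if (dir.exists(p("species"))) {
    sp <- sub("\\.tsv$", "", list.files(p("species"), pattern = "\\.tsv$"))
    bundle$species_expression <- stats::setNames(
      lapply(sp, function(s) read_tsv(p("species", paste0(s, ".tsv")))), sp)
  }
  if (dir.exists(p("zf"))) {
    zf <- list(genes = read_gtf_genes(p("zf", "genes.gtf")),
               embryo_open = read_regions_bed(p("zf", "embryo_open.bed")))
    for (s in c("uninjured", "injured")) {
      zf[[s]] <- list()
      for (r in c("rep1", "rep2"))
        zf[[s]][[r]] <- read_peaks(p("zf", sprintf("%s_%s.bed", s, r)))
    }
    bundle$zf <- zf
  }
  if (has("qpcr.tsv")) bundle$qpcr <- read_tsv(p("qpcr.tsv"))
  if (dir.exists(p("truth"))) {
    tr <- list()
    tp <- function(f) p("truth", f)
    if (file.exists(tp("de.tsv"))) tr$de <- read_tsv(tp("de.tsv"))
    if (file.exists(tp("de_labels.tsv")))
      tr$de_labels <- read_tsv(tp("de_labels.tsv"))$gene_id
    if (file.exists(tp("clusters.tsv"))) {
      cl <- read_tsv(tp("clusters.tsv"))
      cl$members <- strsplit(cl$members, ",", fixed = TRUE)
      tr$clusters <- cl
    }
    if (file.exists(tp("drre.tsv"))) tr$drre <- read_tsv(tp("drre.tsv"))
    if (file.exists(tp("usage.tsv"))) tr$usage <- read_tsv(tp("usage.tsv"))
    if (file.exists(tp("activity.tsv"))) tr$activity <- read_tsv(tp("activity.tsv"))
    if (file.exists(tp("species.tsv"))) tr$species <- read_tsv(tp("species.tsv"))
    if (file.exists(tp("core.tsv"))) tr$core <- read_tsv(tp("core.tsv"))$gene_id
    if (file.exists(tp("zf.tsv"))) tr$zf <- read_tsv(tp("zf.tsv"))
    if (file.exists(tp("qpcr_folds.tsv"))) tr$qpcr_folds <- read_tsv(tp("qpcr_folds.tsv"))
    bundle$truth <- tr
  }
  structure(bundle, class = "sim_bundle")
}
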