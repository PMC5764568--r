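#' INFO key configuration for annotation round-tripping
#'
#' The pipeline carries its annotations (gene, region class, consequence,
#' HGVS, pathogenicity flag, population and internal frequencies) in VCF
#' INFO fields under configurable keys, so annotated call sets are fully
#' self-contained — no external database is queried.
#'
#' @param gene,region_class,consequence,hgvs_c,hgvs_p,pathogenic,internal_freq
#'   INFO key names.
#' @param maf_prefix prefix for per-database minor-allele-frequency keys;
#'   a database `exac` is stored as `MAF_EXAC`.
#' @return A named list of keys.
#' @export
vcf_info_keys <- function(gene = "GENE", region_class = "RC",
                          consequence = "CSQ", hgvs_c = "HGVSC",
                          hgvs_p = "HGVSP", pathogenic = "PATH",
                          internal_freq = "IFREQ", maf_prefix = "MAF_") {
  list(gene = gene, region_class = region_class, consequence = consequence,
       hgvs_c = hgvs_c, hgvs_p = hgvs_p, pathogenic = pathogenic,
       internal_freq = internal_freq, maf_prefix = maf_prefix)
}

parse_info_field <- function(info) {
  if (is.na(info) || info == "." || info == "") return(character(0))
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(parts, 1, eq - 1), parts)
  vals <- ifelse(eq > 0, substr(parts, eq + 1, nchar(parts)), "")
  stats::setNames(vals, keys)
}

#' Read a multi-sample VCF into a variant set
#'
#' Reads VCF 4.x through [vcfR::read.vcfR()], honouring GT, AD, DP and GQ
#' when present, and normalizes records: each multi-allelic record is split
#' into one bi-allelic variant per alternate allele, with allelic depths
#' re-indexed to (ref, this alt). Genotype allele indices pointing at a
#' *different* alternate allele are recoded as 0 (not this alt) in the
#' split record. Annotations are parsed from the configured INFO keys when
#' present, else left unset.
#'
#' @param path VCF file (plain or gzipped).
#' @param info_keys a [vcf_info_keys()] configuration.
#' @return A [variant_set()]; sample order as in the VCF.
#' @export
read_vcf <- function(path, info_keys = vcf_info_keys()) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) {
    empty_sites <- data.frame(vid = integer(0), chrom = character(0),
                              pos = integer(0), id = character(0),
                              ref = character(0), alt = character(0),
                              qual = numeric(0))
    empty_calls <- data.frame(vid = integer(0), sample = character(0),
                              a1 = integer(0), a2 = integer(0),
                              ad_ref = integer(0), ad_alt = integer(0),
                              dp = integer(0), gq = numeric(0))
    return(variant_set(empty_sites, empty_calls, samples = samples))
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop("VCF parse error: non-numeric POS at data line ",
         which(is.na(pos))[1], " of ", path)

  site_rows <- list()
  call_rows <- list()
  vid <- 0L
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) == 0 || any(alts == ""))
      stop("VCF parse error: bad ALT at data line ", r, " of ", path)
    info <- parse_info_field(fix[r, "INFO"])
    fmt <- strsplit(gt[r, 1], ":", fixed = TRUE)[[1]]
    sample_fields <- strsplit(gt[r, -1, drop = TRUE], ":", fixed = TRUE)
    get_field <- function(fields, key) {
      i <- match(key, fmt)
      if (is.na(i) || i > length(fields)) NA_character_ else fields[i]
    }
    for (k in seq_along(alts)) {
      vid <- vid + 1L
      row <- data.frame(
        vid = vid, chrom = fix[r, "CHROM"], pos = pos[r],
        id = if (is.na(fix[r, "ID"]) || fix[r, "ID"] == ".") NA_character_ else fix[r, "ID"],
        ref = fix[r, "REF"], alt = alts[k],
        qual = suppressWarnings(as.numeric(fix[r, "QUAL"])),
        stringsAsFactors = FALSE)
      ik <- info_keys
      row$gene <- if (ik$gene %in% names(info)) info[[ik$gene]] else NA_character_
      row$region_class <- if (ik$region_class %in% names(info)) info[[ik$region_class]] else NA_character_
      row$consequence <- if (ik$consequence %in% names(info)) info[[ik$consequence]] else NA_character_
      row$hgvs_c <- if (ik$hgvs_c %in% names(info)) info[[ik$hgvs_c]] else NA_character_
      row$hgvs_p <- if (ik$hgvs_p %in% names(info)) info[[ik$hgvs_p]] else NA_character_
      row$pathogenic <- ik$pathogenic %in% names(info)
      row$internal_freq <- if (ik$internal_freq %in% names(info))
        as.numeric(info[[ik$internal_freq]]) else NA_real_
      maf_keys <- grep(paste0("^", ik$maf_prefix), names(info), value = TRUE)
      for (mk in maf_keys)
        row[[paste0("maf_", tolower(sub(ik$maf_prefix, "", mk)))]] <-
          as.numeric(info[[mk]])
      site_rows[[vid]] <- row

      for (s in seq_along(samples)) {
        fields <- sample_fields[[s]]
        gt_str <- get_field(fields, "GT")
        a <- strsplit(gsub("|", "/", gt_str, fixed = TRUE), "/", fixed = TRUE)[[1]]
        recode <- function(x) {
          if (is.na(x) || x == ".") return(NA_integer_)
          xi <- as.integer(x)
          if (xi == k) 1L else 0L
        }
        a1 <- if (length(a) >= 1) recode(a[1]) else NA_integer_
        a2 <- if (length(a) >= 2) recode(a[2]) else NA_integer_
        ad_str <- get_field(fields, "AD")
        ad_ref <- ad_alt <- NA_integer_
        if (!is.na(ad_str) && ad_str != ".") {
          ad <- suppressWarnings(as.integer(strsplit(ad_str, ",", fixed = TRUE)[[1]]))
          ad_ref <- ad[1]
          ad_alt <- if (length(ad) >= k + 1) ad[k + 1] else NA_integer_
        }
        dp_str <- get_field(fields, "DP")
        gq_str <- get_field(fields, "GQ")
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          vid = vid, sample = samples[s], a1 = a1, a2 = a2,
          ad_ref = ad_ref, ad_alt = ad_alt,
          dp = if (is.na(dp_str) || dp_str == ".") NA_integer_ else as.integer(dp_str),
          gq = if (is.na(gq_str) || gq_str == ".") NA_real_ else as.numeric(gq_str),
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- do.call(rbind, fill_missing_cols(site_rows))
  calls <- do.call(rbind, call_rows)
  rownames(sites) <- NULL
  rownames(calls) <- NULL
  variant_set(sites, calls, samples = samples)
}

# rbind-safe: give every row data frame the union of columns
fill_missing_cols <- function(rows) {
  all_cols <- unique(unlist(lapply(rows, names)))
  lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA_real_
    r[all_cols]
  })
}

num_str <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Write a variant set as VCF 4.2
#'
#' Emits GT:AD:DP:GQ genotype columns and the package's annotation INFO
#' keys (see [vcf_info_keys()]). Input must be coordinate-sorted.
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @param info_keys a [vcf_info_keys()] configuration.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, info_keys = vcf_info_keys()) {
  sites <- vs$sites
  if (nrow(sites) > 1) {
    by_chrom <- split(sites$pos, factor(sites$chrom, levels = unique(sites$chrom)))
    if (any(vapply(by_chrom, is.unsorted, logical(1))))
      stop("variants must be sorted by (chrom, pos) before writing")
  }
  ik <- info_keys
  maf_cols <- grep("^maf_", names(sites), value = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famfunnel",
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Gene symbol">', ik$gene),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Region class">', ik$region_class),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Coding consequence">', ik$consequence),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="HGVS coding description">', ik$hgvs_c),
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="HGVS protein description">', ik$hgvs_p),
    sprintf('##INFO=<ID=%s,Number=0,Type=Flag,Description="Predicted pathogenic">', ik$pathogenic),
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Internal cohort alternate allele frequency">', ik$internal_freq),
    vapply(maf_cols, function(col) sprintf(
      '##INFO=<ID=%s%s,Number=1,Type=Float,Description="Population MAF (%s)">',
      ik$maf_prefix, toupper(sub("^maf_", "", col)), sub("^maf_", "", col)),
      character(1)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))

  lines <- character(nrow(sites))
  if (nrow(sites) > 0) {
    calls <- vs$calls
    call_key <- paste(calls$vid, calls$sample, sep = "\r")
    for (i in seq_len(nrow(sites))) {
      info <- character(0)
      add <- function(key, val) {
        if (length(val) == 1 && !is.na(val)) c(info, paste0(key, "=", val)) else info
      }
      info <- add(ik$gene, sites$gene[i])
      info <- add(ik$region_class, sites$region_class[i])
      info <- add(ik$consequence, sites$consequence[i])
      info <- add(ik$hgvs_c, sites$hgvs_c[i])
      info <- add(ik$hgvs_p, sites$hgvs_p[i])
      if (isTRUE(sites$pathogenic[i])) info <- c(info, ik$pathogenic)
      info <- add(ik$internal_freq, sites$internal_freq[i])
      for (col in maf_cols)
        info <- add(paste0(ik$maf_prefix, toupper(sub("^maf_", "", col))),
                    sites[[col]][i])
      info_str <- if (length(info) == 0) "." else paste(info, collapse = ";")

      gts <- vapply(vs$samples, function(s) {
        j <- match(paste(sites$vid[i], s, sep = "\r"), call_key)
        if (is.na(j)) return("./.:.:.:.")
        cr <- calls[j, ]
        gt <- if (is.na(cr$a1) || is.na(cr$a2)) "./."
              else paste0(cr$a1, "/", cr$a2)
        ad <- if (is.na(cr$ad_ref) || is.na(cr$ad_alt)) "."
              else paste0(cr$ad_ref, ",", cr$ad_alt)
        paste(gt, ad, num_str(cr$dp), num_str(cr$gq), sep = ":")
      }, character(1))
      lines[i] <- paste(c(sites$chrom[i], sites$pos[i],
                          ifelse(is.na(sites$id[i]), ".", sites$id[i]),
                          sites$ref[i], sites$alt[i], num_str(sites$qual[i]),
                          "PASS", info_str, "GT:AD:DP:GQ", gts),
                        collapse = "\t")
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
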