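`%||%` <- function(a, b) if (is.null(a)) b else a

# write a data.frame as CSV with '#'-prefixed provenance header lines
.write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  # no timestamps: with a fixed seed every pipeline output is byte-identical
  prov <- c(ampelomap = as.character(utils::packageVersion("ampelomap")),
            provenance)
  writeLines(sprintf("# %s: %s", names(prov), unname(prov)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# md5 of a canonical serialization of an R object (config hashing)
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(x, control = "all"), tf)
  unname(tools::md5sum(tf))
}

# derive a reproducible child seed below 2^31 from a base seed and an index
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
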