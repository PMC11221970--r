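# small in-code fixtures shared across test files

tinyCounts <- function() {
  m <- matrix(c(10, 0, 5, 1,
                2, 8, 4, 6,
                7, 3, 9, 2), nrow = 4, ncol = 3,
              dimnames = list(paste0("OTU_", 1:4), c("S1", "S2", "S3")))
  m
}

tinyExperiment <- function() {
  OtuExperiment(tinyCounts(),
                groups = c(S1 = "A", S2 = "A", S3 = "B"),
                taxonomy = data.frame(
                  otu = paste0("OTU_", 1:4),
                  lineage = c("Bacteria;Firmicutes;g__Lactobacillus",
                              "Bacteria;Firmicutes;g__Lactobacillus",
                              "Bacteria;Fusobacteriota;g__Cetobacterium",
                              "unclassified")))
}

writeOtuFixture <- function(m, path, rowsAre = "samples") {
  if (rowsAre == "samples") m <- t(m)      # file rows = samples
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- if (rowsAre == "samples") "sample" else "otu"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# correlation result from an explicit rho matrix (for network unit tests)
corrFromMatrix <- function(rho, n = 30L) {
  diag(rho) <- 1
  new("CorrelationResult", rho = rho,
      p = matrix(0, nrow(rho), ncol(rho), dimnames = dimnames(rho)),
      method = "spearman", nSamples = as.integer(n))
}
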