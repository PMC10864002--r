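# Generates inst/extdata/lm10_synthetic.csv: a synthetic 10-cell-type
# signature matrix (121 genes) used as the packaged deconvolution
# reference. Run once from the repository root; the CSV is committed.
set.seed(20260910)

sig15 <- c("IFIT1", "MX1", "HERC5", "IFI6", "ISG15", "IFIT3", "RSAD2",
           "GBP1", "IFIT2", "XAF1", "PARP9", "UBE2L6", "IRF7", "PARP14",
           "APOL6")
ifng6 <- c("IDO1", "CXCL10", "CXCL9", "HLA-DRA", "STAT1", "IFNG")
background <- sprintf("GENE%03d", seq_len(100))
genes <- c(sig15, ifng6, background)

types <- c("Neut_IFN", "Neutrophil", "Monocyte", "Macrophage", "DC", "NK",
           "Bcell", "TcellCD4", "TcellCD8", "Treg")

base <- rlnorm(length(genes), log(20), 0.5)
P <- sapply(types, function(t) base * rlnorm(length(genes), 0, 0.3))
rownames(P) <- genes

# IFN signature: high in the IFN-stimulated neutrophil state, low in
# baseline neutrophils, near-absent elsewhere
P[sig15, ] <- 1
P[sig15, "Neutrophil"] <- rlnorm(length(sig15), log(8), 0.2)
P[sig15, "Neut_IFN"] <- rlnorm(length(sig15), log(80), 0.2)

# IFN-gamma program: moderate in cytotoxic/NK compartments
P[ifng6, ] <- 2
P[ifng6, c("NK", "TcellCD8")] <- rlnorm(2 * length(ifng6), log(30), 0.2)

# eight exclusive background markers per type for identifiability
marker_blocks <- split(background[seq_len(80)], rep(types, each = 8))
for (t in types) P[marker_blocks[[t]], t] <- rlnorm(8, log(120), 0.2)

P <- round(P, 3)
df <- data.frame(gene_id = genes, P, check.names = FALSE)
write.table(df, "inst/extdata/lm10_synthetic.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
cat("wrote", nrow(df), "genes x", length(types), "types\n")
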