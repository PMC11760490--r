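#!/usr/bin/env Rscript
# Stage 1: build the synthetic study deposit.
#
# Emulates the design of the head-size mapping population: 9 backcross
# families (female channel-line dams x one shared F1 hybrid sire per family),
# 556 offspring, three correlated head traits (length, width, depth)
# confounded with body weight and family, genotyped on a SNP array
# (down-scaled here to 20,000 markers so the whole workflow runs in minutes).
# Seven QTNs are planted at markers that segregate within families: five on
# head length, one on head width, one on head depth — mirroring the 5/1/1
# structure of the study's QTN table. Everything downstream treats the truth
# sidecar as write-only.

suppressMessages(library(grlgwas))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42L

cfg0 <- sim_config(n_snps = 20000, seed = seed,
                   line_maf_distribution = c(0.25, 0.5),
                   missing_pheno_rate = 0.01, missing_geno_rate = 0.005)
geno <- simulate_backcross_genotypes(cfg0)
cat(sprintf("simulated %d individuals x %d SNPs in %d families\n",
            nrow(geno$X), ncol(geno$X), cfg0$n_families))

# plant QTNs where they segregate within families: the within-family
# body-weight adjustment removes between-family genotype contrasts
within_var <- apply(geno$X, 2, function(z) mean(tapply(z, geno$family, var)))
picks <- sort(order(within_var, decreasing = TRUE)[1:7])
qtn <- qtn_spec(picks, a = 0)
qtn[1:5, "a_length"] <- 0.35
qtn[6, "a_width"] <- 0.4
qtn[7, "a_depth"] <- 0.4
cfg <- sim_config(n_snps = 20000, seed = seed,
                  line_maf_distribution = c(0.25, 0.5),
                  missing_pheno_rate = 0.01, missing_geno_rate = 0.005,
                  qtn_spec = qtn)
dat <- simulate_phenotypes(geno, cfg)

files <- write_plink(dat, file.path(out, "catfish_sim"))
cat("wrote:", paste(basename(files), collapse = ", "), "\n")

# synthetic gene annotation: genes tiled near the planted QTNs plus random
# background genes (entirely synthetic labels, for the window-annotation demo)
map <- dat$geno$map
set.seed(seed)
near <- do.call(rbind, lapply(seq_along(picks), function(i) {
  p <- map$bp[picks[i]]
  data.frame(chr = map$chr[picks[i]],
             start = pmax(p + c(-120000, -20000, 180000), 1),
             end = pmax(p + c(-80000, 30000, 260000), 2),
             name = sprintf("syngene_q%d_%d", i, 1:3))
}))
bg_chr <- sample(unique(map$chr), 60, replace = TRUE)
bg_start <- sample.int(max(map$bp), 60)
bg <- data.frame(chr = bg_chr, start = bg_start, end = bg_start + 30000,
                 name = sprintf("syngene_bg%02d", 1:60))
genes <- rbind(near, bg)
writeLines(c("##gff-version 3",
             sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                     genes$chr, genes$start, genes$end, genes$name,
                     genes$name)),
           file.path(out, "synthetic_genes.gff3"))
cat(sprintf("wrote synthetic annotation with %d genes\n", nrow(genes)))

writeLines(as.character(picks), file.path(out, "planted_qtn_indices.txt"))
cat("planted QTN marker indices:", paste(picks, collapse = ", "), "\n")
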