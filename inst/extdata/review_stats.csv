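disease,n_reviews,pct_reviews,n_doctors,pct_doctors,reviews_per_physician,mean_words
infertility,71556,58.31,3573,33.19,20.0,444
infantile pneumonia,21839,17.80,2148,19.96,10.2,435
infantile diarrhea,711,0.60,275,2.60,2.6,499
influenza,1796,1.46,643,6.00,2.8,408
hyperthyroidism,3028,2.47,872,8.10,3.5,383
diabetes,20849,16.99,2627,24.41,7.9,360
liver cancer,1679,1.37,288,2.70,5.8,569
gastric cancer,1053,0.86,231,2.20,4.6,560
hypertension,205,0.20,107,1.00,1.9,369
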