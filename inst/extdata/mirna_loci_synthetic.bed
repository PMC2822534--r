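chr9	94175957	94175979	hsa-let-7f	0	+
chr3	10174452	10174474	hsa-let-7g	0	-
chr5	10223776	10223798	hsa-miR-199a-3p	0	+
chr9	10273608	10273630	hsa-miR-29a	0	-
chr11	10323529	10323551	hsa-let-7a	0	+
chr17	10373683	10373705	hsa-let-7i	0	-
chr22	10423601	10423623	hsa-miR-21	0	+
chrX	10474089	10474110	hsa-miR-152	0	-
chr1	10523504	10523525	hsa-miR-143	0	+
chr3	10573583	10573606	hsa-miR-221	0	-
chr5	10623758	10623781	hsa-miR-103	0	+
chr9	10673479	10673501	hsa-miR-100	0	-
chr11	10724294	10724316	hsa-let-7c	0	+
chr17	10773811	10773833	hsa-let-7e	0	-
chr22	10824056	10824078	hsa-miR-24	0	+
chrX	10873620	10873642	hsa-miR-125b	0	-
chr1	10924077	10924099	hsa-miR-22	0	+
chr3	10973987	10974009	hsa-miR-1	0	-
chr5	11023865	11023887	hsa-miR-320a	0	+
chr9	11074337	11074360	hsa-miR-423-5p	0	-
chr11	11124334	11124356	hsa-miR-185	0	+
chr17	11174354	11174376	hsa-let-7d	0	-
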