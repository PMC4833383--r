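mirna	references
miRNA-29b	ref036
miRNA-30a-5p	ref036
miRNA-140-5p	ref036
miRNA-516-3p	ref036
miRNA-99a	ref036
miRNA-15a	ref037
miRNA-27a	ref037
miRNA-98	ref037
miRNA-103	ref037
miRNA-105	ref037
miRNA-107	ref037
miRNA-122a	ref037
miRNA-128a	ref037
miRNA-134	ref037
miRNA-142-5p	ref037
miRNA-142-3p	ref037
miRNA-1	ref037
miRNA-147	ref037
miRNA-148a	ref037
miRNA-151	ref037
miRNA-181c	ref037
miRNA-186	ref037
miRNA-194	ref037
miRNA-197	ref037
miRNA-213	ref037
miRNA-215	ref037
miRNA-330	ref037
miRNA-338	ref037
miRNA-339	ref037
miRNA-370	ref037
miRNA-373	ref037
miRNA-Let-7g	ref037
miRNA-30e-3p	ref038
miRNA-181d	ref038
miRNA-220	ref038
miRNA-302a	ref038
miRNA-302b	ref038
miRNA-493-3p	ref038
miRNA-550	ref038
miRNA-570	ref038
miRNA-494	ref039
miRNA-500	ref039
miRNA-513a-5p	ref039
miRNA-513b	ref039
miRNA-513c	ref039
miRNA-892b	ref039
miRNA-337	ref040
miRNA-483-3p	ref040
miRNA-520b	ref040
miRNA-520g	ref040
miRNA-550a-3p	ref040
miRNA-629-3p	ref040
miRNA-663	ref040
miRNA-135a-3p	ref040
miRNA-32	ref041
miRNA-33	ref041
miRNA-188	ref041
miRNA-503	ref041
miRNA-542-5p	ref041
miRNA-552	ref041
miRNA-584	ref041
miRNA-625	ref041
miRNA-451	ref042
miRNA-675	ref042
miRNA-424	ref043
miRNA-301b	ref043
miRNA-335	ref044
miRNA-10a	ref036,ref037
miRNA-25	ref036,ref037
miRNA-181a	ref036,ref037
miRNA-200a	ref036,ref037
miRNA-200b	ref036,ref037
miRNA-34a	ref036,ref037
miRNA-141	ref036,ref037
miRNA-320	ref036,ref037
miRNA-93	ref036,ref040
miRNA-298	ref036,ref040
miRNA-30a-3p	ref036,ref044
miRNA-106b	ref036,ref043
miRNA-20	ref046,ref037
miRNA-15b	ref036,ref037,ref044
miRNA-181b	ref036,ref037,ref044
miRNA-210	ref037,ref040
miRNA-221	ref037,ref040
miRNA-154-3p	ref037,ref040
miRNA-182-3p	ref037,ref041
miRNA-374	ref037,ref043
miRNA-191	ref037,ref044
miRNA-200c	ref037,ref044
miRNA-92a-5p	ref038,ref040
miRNA-196b	ref038,ref043
miRNA-19b	ref040,ref042
miRNA-203	ref036,ref037,ref040
miRNA-130b	ref036,ref037,ref040
miRNA-106	ref036,ref037,ref040
miRNA-135a	ref037,ref042,ref045
miRNA-17-3p	ref037,ref040,ref041
miRNA-301	ref037,ref040,ref042
miRNA-92a-3p	ref037,ref040,ref042
miRNA-7	ref038,ref039,ref040
miRNA-18b	ref038,ref040,ref043
miRNA-31	ref036,ref037,ref038,ref041
miRNA-29a	ref036,ref037,ref041,ref042
miRNA-95	ref036,ref037,ref038,ref040
miRNA-17-5p	ref036,ref037,ref038,ref042
miRNA-96	ref036,ref037,ref040,ref041
miRNA-19a	ref036,ref007,ref040,ref043,ref046
miRNA-224	ref036,ref037,ref038,ref041,ref043
miRNA-183	ref036,ref037,ref038,ref040,ref041
miRNA-182-5p	ref036,ref037,ref038,ref040,ref041
miRNA-21	ref036,ref037,ref039,ref040,ref042
miRNA-20a	ref036,ref037,ref040,ref042,ref043
miRNA-18a	ref036,ref038,ref040,ref042,ref043
miRNA-135b	ref037,ref040,ref041,ref043,ref045
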