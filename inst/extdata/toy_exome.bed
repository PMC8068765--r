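ctg01	0	10000
ctg01	20000	30000
ctg01	40000	50000
ctg01	60000	70000
ctg01	80000	90000
ctg01	1e+05	110000
ctg01	120000	130000
ctg01	140000	150000
ctg01	160000	170000
ctg01	180000	190000
ctg02	0	10000
ctg02	20000	30000
ctg02	40000	50000
ctg02	60000	70000
ctg02	80000	90000
ctg02	1e+05	110000
ctg02	120000	130000
ctg02	140000	150000
ctg02	160000	170000
ctg02	180000	190000
ctg03	0	10000
ctg03	20000	30000
ctg03	40000	50000
ctg03	60000	70000
ctg03	80000	90000
ctg03	1e+05	110000
ctg03	120000	130000
ctg03	140000	150000
ctg03	160000	170000
ctg03	180000	190000
ctg04	0	10000
ctg04	20000	30000
ctg04	40000	50000
ctg04	60000	70000
ctg04	80000	90000
ctg04	1e+05	110000
ctg04	120000	130000
ctg04	140000	150000
ctg04	160000	170000
ctg04	180000	190000
ctg05	0	10000
ctg05	20000	30000
ctg05	40000	50000
ctg05	60000	70000
ctg05	80000	90000
ctg05	1e+05	110000
ctg05	120000	130000
ctg05	140000	150000
ctg05	160000	170000
ctg05	180000	190000
ctg06	0	10000
ctg06	20000	30000
ctg06	40000	50000
ctg06	60000	70000
ctg06	80000	90000
ctg06	1e+05	110000
ctg06	120000	130000
ctg06	140000	150000
ctg06	160000	170000
ctg06	180000	190000
ctg07	0	10000
ctg07	20000	30000
ctg07	40000	50000
ctg07	60000	70000
ctg07	80000	90000
ctg07	1e+05	110000
ctg07	120000	130000
ctg07	140000	150000
ctg07	160000	170000
ctg07	180000	190000
ctg08	0	10000
ctg08	20000	30000
ctg08	40000	50000
ctg08	60000	70000
ctg08	80000	90000
ctg08	1e+05	110000
ctg08	120000	130000
ctg08	140000	150000
ctg08	160000	170000
ctg08	180000	190000
ctg09	0	10000
ctg09	20000	30000
ctg09	40000	50000
ctg09	60000	70000
ctg09	80000	90000
ctg09	1e+05	110000
ctg09	120000	130000
ctg09	140000	150000
ctg09	160000	170000
ctg09	180000	190000
ctg10	0	10000
ctg10	20000	30000
ctg10	40000	50000
ctg10	60000	70000
ctg10	80000	90000
ctg10	1e+05	110000
ctg10	120000	130000
ctg10	140000	150000
ctg10	160000	170000
ctg10	180000	190000
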